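# Detector-space utilities: beam-centre finding on SMV images, spot-to-
# reciprocal-space mapping and rotation-axis azimuth refinement.
#
# Pixel convention: 0-based indices, pixel centres at integers, x = fast
# axis (matrix columns), y = slow axis (matrix rows).

#' Experiment geometry
#'
#' @param wavelength Wavelength in Angstrom.
#' @param detector_distance Crystal-to-detector distance in mm.
#' @param pixel_size Pixel edge in mm.
#' @param beam_center `(x, y)` in 0-based pixels.
#' @param rotation_axis_azimuth Spindle azimuth in degrees, counter-clockwise
#'   from +x in the detector plane, in `[-180, 180)`.
#' @param oscillation Degrees of rotation per frame.
#' @param rotation_sign +1 (default) if increasing frame number rotates
#'   counter-clockwise about the axis viewed against the beam, -1 otherwise.
#' @param beamstop_radius Pixels around the beam centre treated as shadowed
#'   (spots inside are skipped when mapping; default 0).
#' @return A list of class `experiment_geometry`.
#' @export
experiment_geometry <- function(wavelength, detector_distance, pixel_size,
                                beam_center, rotation_axis_azimuth = 0,
                                oscillation = 1, rotation_sign = 1,
                                beamstop_radius = 0) {
  if (wavelength <= 0 || detector_distance <= 0 || pixel_size <= 0)
    stop("wavelength, distance and pixel size must be positive")
  az <- ((rotation_axis_azimuth + 180) %% 360) - 180
  structure(list(wavelength = wavelength,
                 detector_distance = detector_distance,
                 pixel_size = pixel_size, beam_center = beam_center,
                 rotation_axis_azimuth = az, oscillation = oscillation,
                 rotation_sign = rotation_sign,
                 beamstop_radius = beamstop_radius),
            class = "experiment_geometry")
}

# sum_x A(x+s) B(x) for all integer shifts s, via zero-padded FFTs
.xcorr_fft <- function(A, B, pad_dim) {
  PA <- matrix(0, pad_dim[1], pad_dim[2])
  PB <- matrix(0, pad_dim[1], pad_dim[2])
  PA[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  PB[seq_len(nrow(B)), seq_len(ncol(B))] <- B
  Re(stats::fft(stats::fft(PA) * Conj(stats::fft(PB)), inverse = TRUE)) /
    prod(pad_dim)
}

.shift_index <- function(s, pad) ifelse(s >= 0, s + 1, pad + s + 1)

#' Find the direct-beam centre on an image
#'
#' Without a beamstop the centre is the intensity centroid of the bright
#' central blob (pixels above half the smoothed maximum). With a beamstop
#' the direct beam is invisible, so the Friedel symmetry of the diffraction
#' pattern is used instead: the normalised masked cross-correlation between
#' the image and its 180-degree-rotated copy is maximised over integer
#' shifts (shadowed pixels, below `floor`, are excluded), and the optimal
#' shift is refined to sub-pixel precision by parabolic interpolation.
#'
#' @param image An `smv_image` (or plain pixel matrix).
#' @param beamstop Logical: use the Friedel-correlation search.
#' @param floor Pixel floor below which pixels count as shadowed
#'   (beamstop mode, default 1).
#' @param max_shift Half-width of the correlation search window in pixels
#'   around the geometric image centre (default 64).
#' @return Centre `c(x, y)` in 0-based pixels.
#' @export
find_beam_center <- function(image, beamstop = FALSE, floor = 1,
                             max_shift = 64) {
  px <- if (inherits(image, "smv_image")) image$pixels else image
  px <- matrix(as.numeric(px), nrow(px), ncol(px))
  if (max(px) - min(px) <= 0) stop("no features: image is flat")
  ny <- nrow(px); nx <- ncol(px)
  xs <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  ys <- matrix(rep(0:(ny - 1), times = nx), ny, nx)
  if (!beamstop) {
    # 3x3 box smoothing to stabilise the maximum against hot pixels
    sm <- px
    sm <- (sm +
             rbind(sm[-1, ], 0) + rbind(0, sm[-ny, ]) +
             cbind(sm[, -1], 0) + cbind(0, sm[, -nx])) / 5
    thr <- min(sm[sm == max(sm)]) * 0.5
    sel <- sm >= thr
    w <- px[sel]
    return(c(sum(xs[sel] * w), sum(ys[sel] * w)) / sum(w))
  }
  M <- (px > floor) * 1
  F1 <- px * M
  rot180 <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
  T2 <- rot180(F1)
  M2 <- rot180(M)
  pad <- c(2^ceiling(log2(2 * ny)), 2^ceiling(log2(2 * nx)))
  n   <- .xcorr_fft(M, M2, pad)
  sF  <- .xcorr_fft(F1, M2, pad)
  sT  <- .xcorr_fft(M, T2, pad)
  sFF <- .xcorr_fft(F1^2, M2, pad)
  sTT <- .xcorr_fft(M, T2^2, pad)
  crs <- .xcorr_fft(F1, T2, pad)
  shifts <- (-max_shift):max_shift
  iy <- .shift_index(shifts, pad[1])
  ix <- .shift_index(shifts, pad[2])
  nn <- pmax(n[iy, ix], 1e-9)
  num <- crs[iy, ix] - sF[iy, ix] * sT[iy, ix] / nn
  den <- sqrt(pmax(sFF[iy, ix] - sF[iy, ix]^2 / nn, 0) *
              pmax(sTT[iy, ix] - sT[iy, ix]^2 / nn, 0))
  ncc <- ifelse(den > 0 & n[iy, ix] > 0.01 * ny * nx, num / den, -Inf)
  pk <- which(ncc == max(ncc), arr.ind = TRUE)[1, ]
  subpix <- function(vals, at) {
    if (at <= 1 || at >= length(vals)) return(0)
    y0 <- vals[at - 1]; y1 <- vals[at]; y2 <- vals[at + 1]
    den <- y0 - 2 * y1 + y2
    if (!is.finite(den) || den >= 0) return(0)
    max(min(0.5 * (y0 - y2) / den, 0.5), -0.5)
  }
  dy <- shifts[pk[1]] + subpix(ncc[, pk[2]], pk[1])
  dx <- shifts[pk[2]] + subpix(ncc[pk[1], ], pk[2])
  # I(x) = R(x - s) with R the 180-degree rotation => centre = (size-1+s)/2
  c((nx - 1 + dx) / 2, (ny - 1 + dy) / 2)
}

#' Map spot centroids to reciprocal-space vectors
#'
#' Each detector spot is projected onto the Ewald sphere (scattering vector
#' `k' - k0` in the laboratory frame) and rotated back by its frame angle
#' about the spindle axis into the common crystal frame. The vector length
#' is `1/d` of the spot's resolution.
#'
#' @param spots Data frame with columns `x`, `y` (0-based pixels), `frame`.
#' @param geometry An [experiment_geometry()].
#' @return n x 3 matrix of reciprocal vectors in 1/Angstrom; attribute
#'   `"n_skipped"` counts spots inside the beamstop radius.
#' @export
spots_to_reciprocal <- function(spots, geometry) {
  gx <- (spots$x - geometry$beam_center[1]) * geometry$pixel_size
  gy <- (spots$y - geometry$beam_center[2]) * geometry$pixel_size
  rpx <- sqrt(gx^2 + gy^2) / geometry$pixel_size
  skip <- rpx < geometry$beamstop_radius & rpx > 0
  keep <- !skip
  D <- geometry$detector_distance
  norm <- sqrt(gx^2 + gy^2 + D^2)
  kl <- 1 / geometry$wavelength
  # lab-frame scattering vector at the moment of observation
  v <- cbind(gx / norm, gy / norm, D / norm - 1) * kl
  v <- v[keep, , drop = FALSE]
  phi <- geometry$rotation_sign * spots$frame[keep] *
    geometry$oscillation * pi / 180
  u <- axis_vector(geometry$rotation_axis_azimuth)
  out <- .rotate_about(v, u, -phi)
  attr(out, "n_skipped") <- sum(skip)
  out
}

# vectorised Rodrigues rotation of row vectors v by per-row angles
.rotate_about <- function(v, u, ang) {
  ca <- cos(ang); sa <- sin(ang)
  dotu <- drop(v %*% u)
  ux_v <- cbind(u[2] * v[, 3] - u[3] * v[, 2],
                u[3] * v[, 1] - u[1] * v[, 3],
                u[1] * v[, 2] - u[2] * v[, 1])
  v * ca + ux_v * sa + outer(dotu * (1 - ca), u)
}

# fraction of back-rotated points whose Friedel antipode coincides within
# `tol` (reciprocal Angstrom); a coarse but broad-basin axis signal
.antipode_score <- function(lab, phi, azimuth_deg, tol = 2e-3) {
  m <- .antipode_match(lab, phi, azimuth_deg, tol)
  mean(!is.na(m))
}

# nearest-cell antipode matching: index of a point whose negated position
# falls in the same or an adjacent quantisation cell, NA when none
.antipode_match <- function(lab, phi, azimuth_deg, tol = 2e-3) {
  v <- .rotate_about(lab, axis_vector(azimuth_deg), -phi)
  q <- round(v / tol)
  M <- 2^20
  keys <- (q[, 1] * M + q[, 2]) * M + q[, 3]
  nkeys <- (-q[, 1] * M - q[, 2]) * M - q[, 3]
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  okeys <- (offs[, 1] * M + offs[, 2]) * M + offs[, 3]
  match_idx <- rep(NA_integer_, nrow(v))
  for (ok in okeys) {
    m <- match(keys + ok, nkeys)
    fill <- is.na(match_idx) & !is.na(m) & m != seq_along(m)
    match_idx[fill] <- m[fill]
  }
  match_idx
}

#' Refine the rotation-axis azimuth
#'
#' Exploits the Friedel self-consistency of the reconstructed reciprocal
#' lattice: a reflection and its Friedel mate cross the (nearly flat) Ewald
#' sphere at slightly different rotation angles, so their back-rotated
#' vectors sum to zero only when the assumed spindle azimuth is correct. A
#' coarse grid scores candidate azimuths by the fraction of points whose
#' antipode coincides within a tolerance; antipodal pairs matched at the
#' coarse optimum are then refined by minimising the mean squared pair
#' residual, which localises the axis far below the coarse step because
#' centroid jitter only adds an azimuth-independent floor.
#'
#' @param spots Data frame with columns `x`, `y`, `frame`; at least 200
#'   spots spanning at least 10 frames.
#' @param geometry An [experiment_geometry()] (its stored azimuth is not
#'   assumed; the whole circle is searched).
#' @param search `"coarse"` (grid only) or `"fine"` (grid + pair
#'   least-squares refinement, default).
#' @param match_tol Antipode coincidence tolerance in reciprocal Angstrom
#'   (default 2e-3).
#' @param coarse_step Coarse grid step in degrees (default 2).
#' @return List with `azimuth` (degrees), `score` (antipode-coincidence
#'   fraction at the solution), `n_pairs`, and the coarse `grid` scores.
#' @export
refine_rotation_axis <- function(spots, geometry, search = c("fine", "coarse"),
                                 match_tol = 2e-3, coarse_step = 2) {
  search <- match.arg(search)
  if (nrow(spots) < 200)
    stop("need at least 200 spots for axis refinement")
  if (length(unique(floor(spots$frame))) < 10)
    stop("insufficient rotation range: spots span fewer than 10 frames")
  gx <- (spots$x - geometry$beam_center[1]) * geometry$pixel_size
  gy <- (spots$y - geometry$beam_center[2]) * geometry$pixel_size
  D <- geometry$detector_distance
  norm <- sqrt(gx^2 + gy^2 + D^2)
  kl <- 1 / geometry$wavelength
  lab <- cbind(gx / norm, gy / norm, D / norm - 1) * kl
  phi <- geometry$rotation_sign * spots$frame * geometry$oscillation * pi / 180

  grid_az <- seq(-180, 180 - coarse_step, by = coarse_step)
  grid_sc <- vapply(grid_az, function(a) .antipode_score(lab, phi, a, match_tol),
                    numeric(1))
  best <- grid_az[which.max(grid_sc)]
  grid <- data.frame(azimuth = grid_az, score = grid_sc)
  if (search == "coarse")
    return(list(azimuth = best, score = max(grid_sc), n_pairs = NA_integer_,
                grid = grid))
  az <- best
  n_pairs <- 0L
  # alternate pair matching and least-squares refinement; the second round
  # re-pairs at the refined axis, where mismatches from the coarse grid
  # have resolved
  for (round in 1:3) {
    mi <- .antipode_match(lab, phi, az, match_tol)
    i <- which(!is.na(mi)); j <- mi[i]
    if (length(i) < 20) {
      if (round == 1) {
        warning("too few Friedel pairs matched; returning the coarse solution")
        return(list(azimuth = best, score = max(grid_sc),
                    n_pairs = length(i), grid = grid))
      }
      break
    }
    n_pairs <- length(i)
    obj <- function(a) {
      v <- .rotate_about(lab, axis_vector(a), -phi)
      mean(rowSums((v[i, , drop = FALSE] + v[j, , drop = FALSE])^2))
    }
    half <- if (round == 1) 2 * coarse_step else 1
    opt <- stats::optimize(obj, c(az - half, az + half), tol = 1e-5)
    if (abs(opt$minimum - az) < 1e-4) { az <- opt$minimum; break }
    az <- opt$minimum
  }
  az <- ((az + 180) %% 360) - 180
  list(azimuth = az, score = .antipode_score(lab, phi, az, match_tol),
       n_pairs = n_pairs, grid = grid)
}
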