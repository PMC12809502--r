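# Synthetic-data generators with known ground truth: Wilson intensities,
# rotation-wedge datasets via an exact Ewald-crossing sweep, planted cluster
# structure, beam images and spot lists. Every generator is deterministic
# under a fixed seed.

#' Generate ground-truth intensities for a synthetic crystal
#'
#' One exponential (Wilson, acentric) intensity per asymmetric-unit orbit in
#' the resolution window, symmetry-consistent by construction.
#'
#' @param cell A [unit_cell()].
#' @param laue A `laue_group`.
#' @param d_min High-resolution limit in Angstrom.
#' @param seed Integer seed.
#' @param d_max Low-resolution limit (default 25 Angstrom).
#' @param mean_intensity Wilson scale (mean of the exponential), default 100.
#' @return An object of class `ed_ground_truth`: list with `cell`, `laue`,
#'   `hkl` (asu representatives), `intensity`, `key`, window and `seed`.
#' @export
make_ground_truth <- function(cell, laue, d_min, seed = 1L, d_max = 25,
                              mean_intensity = 100) {
  grid <- .enumerate_hkl(cell, d_min, d_max, laue$centering)
  if (nrow(grid) == 0) stop("no reflections in the resolution window")
  keys <- asu_key(grid, laue)
  reps <- map_to_asu(grid, laue)
  keep <- !duplicated(keys)
  hkl <- reps[keep, , drop = FALSE]
  key <- keys[keep]
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  intensity <- stats::rexp(nrow(hkl), rate = 1 / mean_intensity)
  structure(list(cell = cell, laue = laue, hkl = hkl, key = key,
                 intensity = intensity, d_min = d_min, d_max = d_max,
                 mean_intensity = mean_intensity, seed = seed),
            class = "ed_ground_truth")
}

#' @export
print.ed_ground_truth <- function(x, ...) {
  cat(sprintf("<ed_ground_truth> %d unique orbits, Laue %s, %.1f-%.2f A\n",
              nrow(x$hkl), x$laue$name, x$d_max, x$d_min))
  invisible(x)
}

#' Specify a synthetic rotation wedge
#'
#' Collects the acquisition and corruption parameters of one synthetic
#' dataset. Defaults describe a clean small-wedge electron-diffraction
#' acquisition.
#'
#' @param phi_start,phi_end Rotation range in degrees (`phi_end > phi_start`).
#' @param oscillation Degrees per frame.
#' @param orientation Crystal setting as three z-y-z Euler angles (radians).
#' @param scale Linear scale factor planted on the dataset.
#' @param b_factor Isotropic B (Angstrom^2), applied as `exp(-2 B s^2)` with
#'   `s = 1/(2d)`.
#' @param error_model `c(a, b)` of the planted noise model
#'   `var = a (sigma^2 + b I^2)`.
#' @param sigma_floor,sigma_frac Reported-sigma model
#'   `sigma = sigma_floor + sigma_frac * I`.
#' @param completeness_fraction Fraction of observed orbits kept.
#' @param outlier_frames Integer frames whose intensities are multiplied by
#'   0.1 (a blocked/bad-frame emulation).
#' @param dose_decay Exponential beam-damage rate per frame (0 = none).
#' @param misindex_op Optional unimodular matrix applied to all indices last
#'   (emulates a mis-indexed dataset).
#' @param wavelength Electron wavelength in Angstrom (default 0.0251, 200 kV).
#' @return A list of class `wedge_spec`.
#' @export
wedge_spec <- function(phi_start = 0, phi_end = 60, oscillation = 0.5,
                       orientation = c(0, 0, 0), scale = 1, b_factor = 0,
                       error_model = c(a = 1, b = 1e-4),
                       sigma_floor = 1, sigma_frac = 0.01,
                       completeness_fraction = 1,
                       outlier_frames = integer(), dose_decay = 0,
                       misindex_op = NULL, wavelength = 0.0251) {
  if (phi_end <= phi_start) stop("empty wedge: phi_end must exceed phi_start")
  if (completeness_fraction <= 0 || completeness_fraction > 1)
    stop("completeness_fraction must be in (0, 1]")
  structure(list(phi_start = phi_start, phi_end = phi_end,
                 oscillation = oscillation, orientation = orientation,
                 scale = scale, b_factor = b_factor,
                 error_model = error_model, sigma_floor = sigma_floor,
                 sigma_frac = sigma_frac,
                 completeness_fraction = completeness_fraction,
                 outlier_frames = as.integer(outlier_frames),
                 dose_decay = dose_decay, misindex_op = misindex_op,
                 wavelength = wavelength),
            class = "wedge_spec")
}

# all distinct symmetry mates (orbit expansion) of the truth's asu reps,
# with the orbit row each mate belongs to
.expand_orbits <- function(truth) {
  ops <- truth$laue$operators
  n <- nrow(truth$hkl)
  mates <- vector("list", length(ops))
  for (i in seq_along(ops))
    mates[[i]] <- cbind(truth$hkl %*% t(ops[[i]]), orbit = seq_len(n))
  all <- do.call(rbind, mates)
  dup <- duplicated(cbind(.hkl_score(all[, 1:3, drop = FALSE]), all[, 4]))
  all[!dup, , drop = FALSE]
}

# exact Ewald-crossing sweep: for each mate, rotation angles (radians,
# relative to phi_start) at which it crosses the sphere within the wedge
.ewald_crossings <- function(hkl, cell, orientation, axis_azimuth,
                             phi_start, phi_end, wavelength) {
  Bm <- recip_basis(cell)
  U <- euler_rotation(orientation)
  xc <- t((U %*% Bm) %*% t(hkl))            # n x 3 lab vectors at phi = 0
  u <- axis_vector(axis_azimuth)
  par <- drop(xc %*% u)                     # component along the axis
  p <- xc - outer(par, u)                   # perpendicular part
  uxp <- cbind(u[2] * p[, 3] - u[3] * p[, 2],
               u[3] * p[, 1] - u[1] * p[, 3],
               u[1] * p[, 2] - u[2] * p[, 1])
  A <- p[, 3]; B <- uxp[, 3]                # z(phi) = A cos + B sin
  r2 <- rowSums(xc^2)
  tgt <- -wavelength * r2 / 2
  R0 <- sqrt(A^2 + B^2)
  ok <- R0 > 0 & abs(tgt) <= R0
  psi <- atan2(B, A)
  dphi <- acos(pmin(pmax(tgt / pmax(R0, 1e-300), -1), 1))
  lo <- (phi_start) * pi / 180
  hi <- (phi_end) * pi / 180
  out <- vector("list", 2)
  res <- list()
  for (sgn in c(1, -1)) {
    phi0 <- psi + sgn * dphi                # solutions mod 2*pi
    # bring every admissible branch into [lo, hi]
    kmin <- ceiling((lo - phi0) / (2 * pi))
    kmax <- floor((hi - phi0) / (2 * pi))
    hit <- ok & (kmax >= kmin)
    if (any(hit)) {
      # wedges are < 360 deg, so at most one k per branch
      phis <- phi0[hit] + 2 * pi * kmin[hit]
      res[[length(res) + 1]] <- data.frame(idx = which(hit), phi = phis)
    }
  }
  if (!length(res)) return(data.frame(idx = integer(), phi = numeric()))
  cr <- do.call(rbind, res)
  # degenerate tangential touch: the two branches coincide
  cr[!duplicated(cbind(cr$idx, round(cr$phi, 9))), , drop = FALSE]
}

#' Generate one synthetic wedge dataset
#'
#' Sweeps the truth's reciprocal lattice through the Ewald sphere over the
#' wedge's rotation range (exact closed-form crossing angles), observes every
#' crossing mate with the planted scale, B factor, dose decay and noise
#' model, then applies outlier frames, orbit thinning and optional
#' mis-indexing.
#'
#' @param truth An `ed_ground_truth`.
#' @param wedge A [wedge_spec()].
#' @param seed Integer seed.
#' @param dataset_id Identifier for the resulting dataset.
#' @param axis_azimuth Spindle-axis azimuth in degrees (default 0).
#' @return List with `record` (an [ed_dataset()]) and `info` (ground-truth
#'   bookkeeping: crossed and kept orbit keys, planted parameters).
#' @export
make_dataset <- function(truth, wedge, seed = 1L, dataset_id = "synthetic",
                         axis_azimuth = 0) {
  stopifnot(inherits(truth, "ed_ground_truth"), inherits(wedge, "wedge_spec"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  mates <- .expand_orbits(truth)
  cr <- .ewald_crossings(mates[, 1:3, drop = FALSE], truth$cell,
                         wedge$orientation, axis_azimuth,
                         wedge$phi_start, wedge$phi_end, wedge$wavelength)
  n_frames <- max(1L, as.integer(ceiling(
    (wedge$phi_end - wedge$phi_start) / wedge$oscillation)))
  if (nrow(cr) == 0) stop("wedge produced no observations")

  hkl <- mates[cr$idx, 1:3, drop = FALSE]
  orbit <- mates[cr$idx, 4]
  frame <- (cr$phi * 180 / pi - wedge$phi_start) / wedge$oscillation
  frame <- pmin(pmax(frame, 0), n_frames)
  d <- d_spacing(hkl, truth$cell)
  s2 <- 1 / (2 * d)^2

  crossed_keys <- unique(truth$key[orbit])
  keep_orbits <- crossed_keys
  if (wedge$completeness_fraction < 1) {
    n_keep <- max(1L, round(length(crossed_keys) * wedge$completeness_fraction))
    keep_orbits <- sample(crossed_keys, n_keep)
  }
  keep <- truth$key[orbit] %in% keep_orbits
  hkl <- hkl[keep, , drop = FALSE]; orbit <- orbit[keep]
  frame <- frame[keep]; s2 <- s2[keep]

  g <- wedge$scale * exp(-2 * wedge$b_factor * s2) *
    exp(-wedge$dose_decay * frame)
  I_true <- truth$intensity[orbit] * g
  sigma <- wedge$sigma_floor + wedge$sigma_frac * abs(I_true)
  a <- wedge$error_model[[1]]; b <- wedge$error_model[[2]]
  noise_sd <- sqrt(a * (sigma^2 + b * I_true^2))
  I_obs <- I_true + stats::rnorm(length(I_true), sd = noise_sd)

  frame_idx <- pmin(floor(frame) + 1L, n_frames)
  bad <- frame_idx %in% wedge$outlier_frames
  I_obs[bad] <- I_obs[bad] * 0.1

  refl <- data.frame(h = as.integer(hkl[, 1]), k = as.integer(hkl[, 2]),
                     l = as.integer(hkl[, 3]), intensity = I_obs,
                     sigma = sigma, frame = frame)
  header <- list(unit_cell = truth$cell,
                 space_group_number = .laue_default_sg(truth$laue$name,
                                                       truth$laue$centering),
                 wavelength = wedge$wavelength,
                 oscillation_per_frame = wedge$oscillation,
                 frame_range = c(0L, n_frames),
                 rotation_axis_azimuth = axis_azimuth)
  record <- ed_dataset(header, refl, dataset_id = dataset_id)
  if (!is.null(wedge$misindex_op))
    record <- reindex(record, wedge$misindex_op)
  list(record = record,
       info = list(crossed_keys = crossed_keys, kept_keys = keep_orbits,
                   n_frames = n_frames, seed = seed, wedge = wedge,
                   axis_azimuth = axis_azimuth))
}

# a representative space-group number for each Laue class/centering (used
# only to stamp synthetic headers)
.laue_default_sg <- function(name, centering = "P") {
  base <- switch(name,
    "-1" = 1L, "2/m" = 3L, "mmm" = 16L, "4/m" = 75L, "4/mmm" = 89L,
    "-3" = 143L, "-3m1" = 150L, "-31m" = 149L, "6/m" = 168L,
    "6/mmm" = 177L, "m-3" = 195L, "m-3m" = 207L)
  # adjust to a centred member where the centering asks for one
  if (centering == "P") return(base)
  cand <- which(.spacegroup_centering == centering)
  cand[vapply(cand, function(s) .spacegroup_laue(s) == name, logical(1))][1]
}

#' Planted two-group cluster fixture
#'
#' Generates wedge datasets from two ground truths that differ either in
#' unit cell (`mode = "cell"`, edges of group B scaled by `1 + separation`)
#' or in intensities (`mode = "intensity"`: independent Wilson draws on the
#' same cell), plus per-dataset cell jitter, and returns the true labels.
#'
#' @param n_a,n_b Group sizes (both >= 2... n_b >= 1 is rejected below 2 for
#'   the planted-partition tests to make sense).
#' @param separation Relative cell difference between the groups (cell mode).
#' @param seed Integer seed.
#' @param mode `"cell"` or `"intensity"`.
#' @param cell Base cell (default a generic triclinic 10/12/15 cell).
#' @param laue Laue group (default `-1`).
#' @param d_min Resolution limit of the truths.
#' @param cell_jitter Relative per-dataset jitter on header cell edges
#'   (default 0.002).
#' @return List with `records` (list of `ed_dataset`) and `labels`.
#' @export
make_cluster_fixture <- function(n_a, n_b, separation = 0.05, seed = 1L,
                                 mode = c("intensity", "cell"),
                                 cell = unit_cell(10, 12, 15, 85, 95, 100),
                                 laue = laue_operators("-1"),
                                 d_min = 1.5, cell_jitter = 0.002) {
  mode <- match.arg(mode)
  if (n_a < 2 || n_b < 2) stop("need at least two datasets per group")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  cell_b <- if (mode == "cell")
    unit_cell(cell[["a"]] * (1 + separation), cell[["b"]] * (1 + separation),
              cell[["c"]] * (1 + separation),
              cell[["alpha"]], cell[["beta"]], cell[["gamma"]])
  else cell
  truth_a <- make_ground_truth(cell, laue, d_min, seed = seed)
  truth_b <- make_ground_truth(cell_b, laue, d_min, seed = seed + 1000L)
  labels <- rep(c("A", "B"), c(n_a, n_b))
  records <- vector("list", n_a + n_b)
  for (i in seq_along(labels)) {
    tr <- if (labels[i] == "A") truth_a else truth_b
    w <- wedge_spec(phi_start = 0, phi_end = 70, oscillation = 0.5,
                    orientation = stats::runif(3, 0, 2 * pi),
                    error_model = c(a = 1, b = 2.5e-3))
    ds <- make_dataset(tr, w, seed = seed + 10L * i,
                       dataset_id = sprintf("%s%02d", tolower(labels[i]), i))
    rec <- ds$record
    if (cell_jitter > 0) {
      uc <- rec$header$unit_cell
      j <- 1 + stats::rnorm(3, 0, cell_jitter)
      rec$header$unit_cell <- unit_cell(uc[["a"]] * j[1], uc[["b"]] * j[2],
                                        uc[["c"]] * j[3], uc[["alpha"]],
                                        uc[["beta"]], uc[["gamma"]])
    }
    records[[i]] <- rec
  }
  list(records = records, labels = labels,
       cells = c(list(cell), list(cell_b)))
}

#' Synthetic beam image
#'
#' Poisson background plus either a bright Gaussian direct beam (no
#' beamstop) or a Friedel-symmetric spot field with a wedge-shaped beamstop
#' shadow (pixels set to zero).
#'
#' @param center True beam centre `(x, y)` in 0-based pixels.
#' @param beamstop Logical; `TRUE` plants the symmetric spot field plus
#'   shadow instead of the direct beam.
#' @param seed Integer seed.
#' @param size Image side in pixels (square, default 256).
#' @param background Poisson background mean (default 20).
#' @return List with `image` (an `smv_image`) and `truth` (the centre).
#' @export
make_beam_image <- function(center, beamstop = FALSE, seed = 1L, size = 256L,
                            background = 20) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  px <- matrix(stats::rpois(size * size, background), size, size)
  xs <- matrix(rep(0:(size - 1), each = size), size, size)  # column = x
  ys <- matrix(rep(0:(size - 1), times = size), size, size) # row = y
  gauss <- function(cx, cy, amp, sd)
    amp * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sd^2))
  if (!beamstop) {
    px <- px + round(gauss(center[1], center[2], 40000, 3))
  } else {
    n_spots <- 120
    ang <- stats::runif(n_spots, 0, 2 * pi)
    rad <- stats::runif(n_spots, 15, size * 0.45)
    sx <- center[1] + rad * cos(ang)
    sy <- center[2] + rad * sin(ang)
    amp <- stats::runif(n_spots, 3000, 12000)
    for (i in seq_len(n_spots)) {
      px <- px + round(gauss(sx[i], sy[i], amp[i], 1.4))
      px <- px + round(gauss(2 * center[1] - sx[i], 2 * center[2] - sy[i],
                             amp[i], 1.4))
    }
    # wedge-shaped beamstop shadow from the centre towards +x
    theta <- atan2(ys - center[2], xs - center[1])
    shadow <- abs(theta) < (25 * pi / 180)
    px[shadow] <- 0
  }
  px[px > 65535] <- 65535
  header <- c(HEADER_BYTES = "512", DIM = "2", BYTE_ORDER = "little_endian",
              TYPE = "unsigned_short",
              SIZE1 = as.character(size), SIZE2 = as.character(size),
              PIXEL_SIZE = "0.055", DISTANCE = "958",
              WAVELENGTH = "0.0251", OSC_START = "0", OSC_RANGE = "0.23",
              BEAM_CENTER_X = sprintf("%.4f", center[1] * 0.055),
              BEAM_CENTER_Y = sprintf("%.4f", center[2] * 0.055))
  storage.mode(px) <- "integer"
  img <- structure(list(header = header, pixels = px), class = "smv_image")
  list(image = img, truth = center)
}

#' Synthetic spot-centroid list
#'
#' Exact Ewald-crossing detector positions of a crystal rotated about a
#' planted spindle azimuth, with sub-pixel centroid jitter. Substrate for
#' rotation-axis refinement.
#'
#' @param cell A [unit_cell()].
#' @param orientation Euler angles (radians) of the crystal setting.
#' @param phi_axis Planted spindle azimuth in degrees.
#' @param geometry An [experiment_geometry()].
#' @param seed Integer seed.
#' @param d_min Resolution limit of generated spots (default 1.0).
#' @param phi_range Total rotation range in degrees (default 60).
#' @param jitter Centroid jitter sigma in pixels (default 0.3).
#' @return List with `spots` (data frame `x, y, frame, intensity`) and
#'   `truth` (planted azimuth and inputs).
#' @export
make_spot_list <- function(cell, orientation, phi_axis, geometry, seed = 1L,
                           d_min = 1.0, phi_range = 60, jitter = 0.3) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  grid <- .enumerate_hkl(cell, d_min)
  cr <- .ewald_crossings(grid, cell, orientation, phi_axis,
                         0, phi_range, geometry$wavelength)
  if (nrow(cr) == 0) stop("no spots generated; enlarge the wedge")
  hkl <- grid[cr$idx, , drop = FALSE]
  Bm <- recip_basis(cell)
  U <- euler_rotation(orientation)
  xc <- t((U %*% Bm) %*% t(hkl))
  u <- axis_vector(phi_axis)
  lab <- t(vapply(seq_len(nrow(xc)), function(i)
    drop(rot_about_axis(u, cr$phi[i]) %*% xc[i, ]), numeric(3)))
  kz <- 1 / geometry$wavelength
  kp <- cbind(lab[, 1], lab[, 2], lab[, 3] + kz)
  ok <- kp[, 3] > 0
  kp <- kp[ok, , drop = FALSE]
  phi <- cr$phi[ok]
  scale <- geometry$detector_distance / geometry$pixel_size
  x <- geometry$beam_center[1] + kp[, 1] / kp[, 3] * scale +
    stats::rnorm(nrow(kp), 0, jitter)
  y <- geometry$beam_center[2] + kp[, 2] / kp[, 3] * scale +
    stats::rnorm(nrow(kp), 0, jitter)
  frame <- (phi * 180 / pi) / geometry$oscillation
  inb <- x >= 0 & y >= 0
  spots <- data.frame(x = x[inb], y = y[inb], frame = frame[inb],
                      intensity = stats::rexp(sum(inb), 1 / 500))
  list(spots = spots,
       truth = list(phi_axis = phi_axis, orientation = orientation,
                    cell = cell, seed = seed))
}
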