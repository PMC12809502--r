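# Dataset selection, inter-dataset scaling, outlier-frame exclusion and
# merging to a unique reflection list.

#' Quality thresholds for dataset selection
#'
#' Batch defaults follow the promising-dataset rule (ISa > 5, CC1/2 > 95%,
#' completeness > 80%); the real-time profile relaxes CC1/2 to 90% and drops
#' the completeness requirement, since small wedges are individually
#' incomplete by design.
#'
#' @param isa_min Minimum ISa (default 5).
#' @param cc_half_min Minimum CC1/2 in percent (default 95).
#' @param completeness_min Minimum completeness in percent (default 80).
#' @return A named list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(isa_min = 5, cc_half_min = 95,
                              completeness_min = 80) {
  if (any(c(isa_min, cc_half_min, completeness_min) < 0))
    stop("thresholds must be non-negative")
  structure(list(isa_min = isa_min, cc_half_min = cc_half_min,
                 completeness_min = completeness_min),
            class = "filter_thresholds")
}

#' @rdname filter_thresholds
#' @export
realtime_thresholds <- function(isa_min = 5, cc_half_min = 90,
                                completeness_min = 0) {
  filter_thresholds(isa_min = isa_min, cc_half_min = cc_half_min,
                    completeness_min = completeness_min)
}

#' Select datasets for merging by quality thresholds
#'
#' A dataset is picked when it meets every threshold; a missing indicator
#' counts as a failure and is recorded in the reason. Input order is
#' preserved.
#'
#' @param rows Summary data frame (one row per dataset, see
#'   [dataset_summary()]).
#' @param thresholds A [filter_thresholds()].
#' @return List with `picked` (dataset ids), `rejected` (ids) and `reasons`
#'   (named character vector for the rejected ids).
#' @export
filter_datasets <- function(rows, thresholds = filter_thresholds()) {
  if (nrow(rows) == 0) stop("no summary rows to filter")
  reasons <- character(0)
  picked <- character(0)
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    why <- character(0)
    chk <- function(val, min, label) {
      if (min <= 0) return(character(0))
      if (is.na(val)) sprintf("%s missing", label)
      else if (val < min) sprintf("%s<%g", label, min)
      else character(0)
    }
    why <- c(chk(r$isa, thresholds$isa_min, "ISa"),
             chk(r$cc_half, thresholds$cc_half_min, "CC1/2"),
             chk(r$completeness, thresholds$completeness_min, "completeness"))
    if (length(why)) reasons[r$dataset_id] <- paste(why, collapse = "; ")
    else picked <- c(picked, r$dataset_id)
  }
  list(picked = picked, rejected = names(reasons), reasons = reasons)
}

# union-find connectivity over pairwise common-orbit counts
.check_connected <- function(keys_list, min_common, ids) {
  n <- length(keys_list)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sum(keys_list[[i]] %in% keys_list[[j]]) >= min_common) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  if (length(unique(roots)) > 1) {
    comp <- split(ids, roots)
    stop("datasets are not connected by common reflections (min_common = ",
         min_common, "); components: ",
         paste(vapply(comp, paste, "", collapse = "+"), collapse = " | "))
  }
  invisible(TRUE)
}

#' Fit inter-dataset scale factors
#'
#' Alternating least squares for the zero-dimensional scaling model
#' `I_obs = k_i * exp(-2 B_i s^2) * <I>_u`: given current merged means, each
#' dataset's scale (and B when `with_b`) is updated by weighted least
#' squares, the means are re-merged, and the loop runs to a relative
#' parameter change below `tol`. The gauge is fixed to geometric mean
#' `k = 1` (and mean `B = 0`).
#'
#' @param datasets List of [ed_dataset()] objects.
#' @param laue A `laue_group`.
#' @param with_b Fit per-dataset isotropic B factors (default `FALSE`).
#' @param min_common Pairwise connectivity requirement (default 20).
#' @param max_iter Iteration cap (default 100).
#' @param tol Relative-change convergence tolerance (default 1e-6).
#' @return Object of class `scale_solution`: `k`, `b` (named per dataset),
#'   `excluded_frames` (empty; see [exclude_outlier_frames()]),
#'   `n_iter`, `converged`.
#' @export
fit_scales <- function(datasets, laue, with_b = FALSE, min_common = 20,
                       max_iter = 100, tol = 1e-6) {
  n <- length(datasets)
  if (n < 2) stop("need at least two datasets to scale")
  ids <- vapply(datasets, function(d) d$dataset_id, character(1))
  grs <- lapply(datasets, function(d) group_equivalents(d$reflections, laue))
  .check_connected(lapply(grs, function(g) unique(g$key)), min_common, ids)

  key <- unlist(lapply(grs, function(g) g$key))
  I <- unlist(lapply(datasets, function(d) d$reflections$intensity))
  sg <- unlist(lapply(datasets, function(d) d$reflections$sigma))
  ds <- rep(seq_len(n), vapply(datasets, function(d) nrow(d$reflections), 0L))
  d_sp <- unlist(lapply(datasets, function(d)
    d_spacing(as.matrix(d$reflections[, c("h", "k", "l")]),
              d$header$unit_cell)))
  s2 <- 1 / (2 * d_sp)^2
  uk <- sort(unique(key))
  g <- match(key, uk)

  k <- rep(1, n); b <- rep(0, n)
  delta <- Inf
  w0 <- 1 / sg^2
  for (iter in seq_len(max_iter)) {
    gfac <- k[ds] * exp(-2 * b[ds] * s2)
    # merged means of descaled intensities, inverse-variance weighted
    w <- w0 * gfac^2
    M <- rowsum(w * I / gfac, g)[, 1] / rowsum(w, g)[, 1]
    Mg <- M[g]
    k_new <- k; b_new <- b
    for (i in seq_len(n)) {
      sel <- ds == i
      if (!with_b) {
        k_new[i] <- sum(w0[sel] * I[sel] * Mg[sel]) /
          sum(w0[sel] * Mg[sel]^2)
      } else {
        ok <- sel & I > 0 & Mg > 0
        y <- log(I[ok] / Mg[ok])
        x <- s2[ok]
        W <- (I[ok] / sg[ok])^2        # delta-method weight for log I
        sw <- sum(W); mx <- sum(W * x) / sw; my <- sum(W * y) / sw
        vxx <- sum(W * (x - mx)^2)
        slope <- if (vxx > 0) sum(W * (x - mx) * (y - my)) / vxx else 0
        b_new[i] <- -slope / 2
        k_new[i] <- exp(my - slope * mx)
      }
    }
    if (any(!is.finite(k_new)) || any(k_new <= 0))
      stop("scale fit diverged: non-positive scale")
    # gauge fixing
    k_new <- k_new / exp(mean(log(k_new)))
    if (with_b) b_new <- b_new - mean(b_new)
    delta <- max(abs(k_new - k) / pmax(abs(k), 1e-12),
                 if (with_b) abs(b_new - b) * max(s2) else 0)
    k <- k_new; b <- b_new
    if (delta < tol) break
  }
  converged <- delta < tol
  if (!converged)
    warning("scale refinement did not converge in ", max_iter,
            " iterations (last change ", signif(delta, 3), ")")
  structure(list(k = stats::setNames(k, ids), b = stats::setNames(b, ids),
                 excluded_frames = stats::setNames(
                   rep(list(data.frame(from = integer(), to = integer())), n), ids),
                 n_iter = iter, converged = converged, with_b = with_b),
            class = "scale_solution")
}

#' @export
print.scale_solution <- function(x, ...) {
  cat(sprintf("<scale_solution> %d datasets, %d iterations%s\n",
              length(x$k), x$n_iter,
              if (x$converged) "" else " (not converged)"))
  print(round(rbind(k = x$k, B = x$b), 4))
  invisible(x)
}

#' Detect and exclude outlier frames
#'
#' Computes a per-frame relative scale (median ratio of each frame's
#' observations to their orbit means), detrends it with a running median, and
#' excludes frames whose log-scale deviates more than `n_sigma` robust (MAD)
#' standard deviations. Smooth decay, e.g. accumulating beam damage, is
#' absorbed by the running median and yields no exclusions.
#'
#' @param dataset An [ed_dataset()] with frame coordinates and >= 20 frames.
#' @param laue A `laue_group` for the equivalence grouping (defaults to the
#'   header's space group).
#' @param window Running-median window in frames (odd, default 15).
#' @param n_sigma Robust-deviation threshold (default 3).
#' @param min_deviation Absolute log-scale deviation floor (default 0.3,
#'   i.e. a frame must be at least ~35 percent off its local trend to be
#'   excluded; guards against flagging statistically tight data).
#' @return Data frame of excluded contiguous ranges (`from`, `to`, 1-based
#'   frame indices); attribute `"frame_scale"` carries the per-frame table.
#' @export
exclude_outlier_frames <- function(dataset, laue = NULL, window = 15,
                                   n_sigma = 3, min_deviation = 0.3) {
  if (dataset$frameless) {
    warning("dataset is frameless; no per-frame exclusion possible")
    return(data.frame(from = integer(), to = integer()))
  }
  if (is.null(laue)) laue <- laue_for_spacegroup(dataset$header$space_group_number)
  refl <- dataset$reflections
  nf <- max(1L, as.integer(ceiling(max(refl$frame))))
  if (nf < 20) stop("need at least 20 frames for outlier screening")
  gr <- group_equivalents(refl, laue)
  frame_idx <- pmin(pmax(floor(refl$frame) + 1L, 1L), nf)
  bad <- integer()
  fscale <- NULL; frames <- NULL
  # re-flag until stable: orbit means are recomputed without observations on
  # currently flagged frames, so one bad frame cannot drag its orbit
  # partners' frames over the threshold
  for (pass in 1:5) {
    use <- !(frame_idx %in% bad)
    uk <- sort(unique(gr$key))
    gu <- match(gr$key, uk)
    n_u <- tabulate(gu[use], nbins = length(uk))
    sum_u <- rowsum(refl$intensity * use, factor(gu, levels = seq_along(uk)))[, 1]
    # leave-one-out reference: each observation is rated against the mean of
    # the *other* usable observations of its orbit
    n_ref <- n_u[gu] - use
    ref <- (sum_u[gu] - refl$intensity * use) / pmax(n_ref, 1)
    ratio <- refl$intensity / ref
    ok <- n_ref >= 1 & is.finite(ratio) & ratio > 0
    fscale <- tapply(ratio[ok], frame_idx[ok], stats::median)
    frames <- as.integer(names(fscale))
    lg <- log(fscale)
    kk <- min(window, length(lg))
    if (kk %% 2 == 0) kk <- kk - 1
    kk <- max(kk, 3)
    trend <- stats::runmed(lg, k = kk)
    resid <- lg - trend
    rsd <- stats::mad(resid)
    bad_new <- frames[abs(resid) > max(n_sigma * rsd, min_deviation)]
    if (identical(bad_new, bad)) break
    bad <- bad_new
  }
  ranges <- if (length(bad)) {
    brk <- c(0, which(diff(bad) > 1), length(bad))
    do.call(rbind, lapply(seq_len(length(brk) - 1), function(i)
      data.frame(from = bad[brk[i] + 1], to = bad[brk[i + 1]])))
  } else data.frame(from = integer(), to = integer())
  attr(ranges, "frame_scale") <- data.frame(frame = frames, scale = fscale,
                                            trend = exp(trend))
  ranges
}

#' Scale and merge datasets to a unique reflection list
#'
#' Applies the scale solution (intensities divided by
#' `k_i exp(-2 B_i s^2)`), drops observations on excluded frames, merges
#' each orbit by inverse-variance weighted mean, inflates merged sigmas with
#' the error model fitted on the scaled observations, and computes full
#' shell statistics on the merged set.
#'
#' @param datasets List of [ed_dataset()] objects.
#' @param solution A `scale_solution` covering every dataset (or `NULL` for
#'   unit scales).
#' @param laue A `laue_group`.
#' @param excluded Optional named list (per dataset id) of exclusion range
#'   data frames from [exclude_outlier_frames()].
#' @param n_shells Shell count for the merged statistics.
#' @param seed Seed for the half-set splits.
#' @return List with `merged` (a merged [ed_dataset()]), `shells`
#'   (`shell_stats`), `error_model`, and `n_obs_used`.
#' @export
merge_datasets <- function(datasets, solution = NULL, laue,
                           excluded = NULL, n_shells = 10, seed = 42L) {
  ids <- vapply(datasets, function(d) d$dataset_id, character(1))
  if (!is.null(solution)) {
    missing_ids <- setdiff(ids, names(solution$k))
    if (length(missing_ids))
      stop("scale solution lacks datasets: ", paste(missing_ids, collapse = ", "))
  }
  cell <- datasets[[1]]$header$unit_cell
  tabs <- lapply(datasets, function(d) {
    refl <- d$reflections
    if (!is.null(excluded) && !is.null(excluded[[d$dataset_id]])) {
      ex <- excluded[[d$dataset_id]]
      if (nrow(ex)) {
        fi <- floor(refl$frame) + 1
        drop <- rep(FALSE, nrow(refl))
        for (r in seq_len(nrow(ex)))
          drop <- drop | (fi >= ex$from[r] & fi <= ex$to[r])
        refl <- refl[!drop, , drop = FALSE]
      }
    }
    if (!is.null(solution)) {
      dsp <- d_spacing(as.matrix(refl[, c("h", "k", "l")]), d$header$unit_cell)
      s2 <- 1 / (2 * dsp)^2
      gfac <- solution$k[[d$dataset_id]] *
        exp(-2 * solution$b[[d$dataset_id]] * s2)
      refl$intensity <- refl$intensity / gfac
      refl$sigma <- refl$sigma / gfac
    }
    refl
  })
  all <- do.call(rbind, tabs)
  gr <- group_equivalents(all, laue)
  em <- fit_error_model(gr)

  key <- gr$key
  uk <- sort(unique(key))
  g <- match(key, uk)
  w <- 1 / all$sigma^2
  sw <- rowsum(w, g)[, 1]
  Im <- rowsum(w * all$intensity, g)[, 1] / sw
  sm <- sqrt(1 / sw)
  if (!is.na(em$isa))
    sm <- sqrt(em$a * (sm^2 + em$b * Im^2))
  first <- !duplicated(key)
  asu_first <- gr$asu[first, , drop = FALSE]
  ord <- match(uk, key[first])
  hkl_u <- asu_first[ord, , drop = FALSE]

  merged_refl <- data.frame(h = hkl_u[, 1], k = hkl_u[, 2], l = hkl_u[, 3],
                            intensity = Im, sigma = pmax(sm, 1e-12),
                            frame = NA_real_)
  hd <- datasets[[1]]$header
  hd$frame_range <- c(0L, 1L)
  merged <- ed_dataset(hd, merged_refl, dataset_id = "merged", merged = TRUE)
  shells <- bin_shells(all, cell, laue, n_shells = n_shells, seed = seed)
  list(merged = merged, shells = shells, error_model = em,
       n_obs_used = nrow(all))
}
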