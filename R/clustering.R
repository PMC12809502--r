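# Dataset grouping: unit-cell similarity clustering, Laue-group estimation,
# pairwise intensity-correlation matrices and correlation clustering with
# disX-clsY group naming.

#' Distance matrix between unit cells
#'
#' Euclidean distance between feature vectors (a, b, c in Angstrom and the
#' three angles scaled by `w_angle` Angstrom/degree) of Niggli-reduced cells,
#' so alternative axis choices of the same lattice compare as identical.
#'
#' @param cells List of [unit_cell()] objects.
#' @param w_angle Angle weight in Angstrom per degree (default 0.5).
#' @param reduce Niggli-reduce before comparing (default `TRUE`).
#' @param ids Optional dataset identifiers.
#' @return Object of class `distance_matrix`: list with `ids` and symmetric
#'   matrix `d`.
#' @export
cell_distance_matrix <- function(cells, w_angle = 0.5, reduce = TRUE,
                                 ids = NULL) {
  if (length(cells) < 2) stop("need at least two cells")
  if (is.null(ids)) ids <- sprintf("cell_%d", seq_along(cells))
  if (reduce) cells <- lapply(cells, niggli_reduce)
  feat <- t(vapply(cells, function(uc)
    c(uc[["a"]], uc[["b"]], uc[["c"]],
      w_angle * uc[["alpha"]], w_angle * uc[["beta"]], w_angle * uc[["gamma"]]),
    numeric(6)))
  d <- as.matrix(stats::dist(feat))
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d), class = "distance_matrix")
}

.threshold_label <- function(x) {
  # compact numeric tag used in disX-clsY names (0.5 -> "0.5", 2 -> "2")
  sub("\\.?0+$", "", sprintf("%.4f", x))
}

.cut_and_name <- function(hc, ids, threshold) {
  memb <- stats::cutree(hc, h = threshold)
  sizes <- table(memb)
  ord <- order(-as.vector(sizes), as.integer(names(sizes)))
  groups <- lapply(as.integer(names(sizes))[ord],
                   function(g) ids[memb == g])
  names(groups) <- sprintf("dis%s-cls%d", .threshold_label(threshold),
                           seq_along(groups))
  structure(list(linkage = cbind(hc$merge, height = hc$height,
                                 size = .merge_sizes(hc)),
                 hclust = hc, threshold = threshold, groups = groups,
                 ids = ids),
            class = "cluster_result")
}

.merge_sizes <- function(hc) {
  n <- length(hc$order)
  sz <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    m <- hc$merge[i, ]
    sz[i] <- sum(ifelse(m < 0, 1, sz[pmax(m, 1)]))
  }
  sz
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> threshold %g: %d group(s)\n",
              x$threshold, length(x$groups)))
  for (nm in names(x$groups))
    cat(sprintf("  %s: %s\n", nm, paste(x$groups[[nm]], collapse = ", ")))
  invisible(x)
}

#' Cluster datasets by unit-cell similarity
#'
#' Average-linkage hierarchical clustering of a cell distance matrix, cut at
#' a threshold; groups are named `disX-clsY` with X the threshold and Y the
#' group rank by size (largest first).
#'
#' @param matrix A `distance_matrix` from [cell_distance_matrix()].
#' @param threshold Cut height (same units as the distances).
#' @param method Linkage (default `"average"`).
#' @return A `cluster_result`.
#' @export
cluster_cells <- function(matrix, threshold, method = "average") {
  hc <- stats::hclust(stats::as.dist(matrix$d), method = method)
  .cut_and_name(hc, matrix$ids, threshold)
}

#' Estimate the Laue group of a dataset
#'
#' Scores each candidate Laue class with four indicators: (1) Rmeas under
#' the candidate; (2) the ratio of that Rmeas to the Friedel-only (-1)
#' Rmeas; (3) CC1/2 under the candidate with its significance; (4) the
#' correlation between candidate-merged and Friedel-only-merged mean
#' intensities on common unique reflections. Candidates with Rmeas ratio
#' above `ratio_max` or non-significant CC1/2 are rejected (`-1` is the
#' reference hypothesis and always survives, consistent with Friedel pairs
#' being merged throughout); accepted candidates within `cc_tol` percent of
#' the best CC1/2 are ranked highest symmetry first.
#'
#' @param record An [ed_dataset()].
#' @param candidates Character vector of Laue class names (default: all that
#'   are metrically sensible is the caller's concern; the full list is used).
#' @param ratio_max Rmeas-ratio rejection bound (default 2).
#' @param cc_tol Tolerance in CC1/2 percent for "as good as the best"
#'   (default 2).
#' @param seed Seed for the half-set splits.
#' @return Data frame of class `laue_scores`, ranked; attribute `"best"`
#'   holds the top accepted class name.
#' @export
estimate_laue <- function(record, candidates = c("-1", "2/m", "mmm"),
                          ratio_max = 2, cc_tol = 2, seed = 42L) {
  refl <- record$reflections
  if (!"-1" %in% candidates) candidates <- c("-1", candidates)
  base <- group_equivalents(refl, laue_operators("-1"))
  r_base <- r_meas(base)
  base_means <- .orbit_means(base)
  rows <- lapply(candidates, function(nm) {
    laue <- laue_operators(nm)
    gr <- group_equivalents(refl, laue)
    rm <- r_meas(gr)
    cc <- cc_half(gr, seed = seed)
    # indicator 4: agreement of candidate-merged vs Friedel-merged means,
    # the latter averaged within each candidate orbit
    cand_means <- .orbit_means(gr)
    grp <- asu_key(base_means$hkl, laue)
    agg <- tapply(base_means$mean, grp, mean)
    idx <- match(cand_means$key, as.numeric(names(agg)))
    okk <- !is.na(idx)
    cc_merge <- if (sum(okk) >= 3)
      suppressWarnings(stats::cor(cand_means$mean[okk], agg[idx[okk]]))
    else NA_real_
    n_ops <- length(laue$operators)
    ratio <- rm / r_base
    # "-1" is the reference hypothesis (Friedel merging is always assumed)
    accepted <- nm == "-1" ||
      (is.finite(ratio) && ratio <= ratio_max &&
       !is.na(cc$cc) && cc$significant)
    data.frame(candidate = nm, n_operators = n_ops,
               r_meas = rm, r_meas_ratio = ratio,
               cc_half = cc$cc, cc_significant = cc$significant,
               cc_vs_friedel = cc_merge,
               verdict = if (accepted) "accepted" else "rejected",
               stringsAsFactors = FALSE)
  })
  sc <- do.call(rbind, rows)
  if (!any(sc$verdict == "accepted"))
    stop("no candidate Laue group is computable/acceptable for this dataset")
  acc <- sc[sc$verdict == "accepted", ]
  best_cc <- max(acc$cc_half, na.rm = TRUE)
  acc$near_best <- acc$cc_half >= best_cc - cc_tol
  # highest symmetry first among near-best, then by CC; rejected last
  acc <- acc[order(-acc$near_best, -acc$n_operators, -acc$cc_half), ]
  rej <- sc[sc$verdict == "rejected", ]
  if (nrow(rej)) rej$near_best <- FALSE
  out <- rbind(acc, rej)
  rownames(out) <- NULL
  attr(out, "best") <- acc$candidate[1]
  class(out) <- c("laue_scores", "data.frame")
  out
}

# unique-orbit mean intensities of a refl_groups
.orbit_means <- function(groups) {
  gt <- .group_table(groups)
  first <- !duplicated(groups$key)
  hkl <- groups$asu[first, , drop = FALSE]
  key_first <- groups$key[first]
  ord <- match(gt$uk, key_first)
  list(key = gt$uk, hkl = hkl[ord, , drop = FALSE], mean = gt$mean, n = gt$n)
}

#' Pairwise intensity correlation between datasets
#'
#' Each dataset is first merged internally to unique-orbit mean intensities
#' under the common Laue group; for every pair the Pearson correlation over
#' common unique reflections is computed. Pairs with fewer than `min_common`
#' common reflections are reported missing rather than zero.
#'
#' @param datasets List of [ed_dataset()] objects.
#' @param laue A `laue_group`.
#' @param min_common Minimum number of common unique reflections (default 20).
#' @return A `correlation_table` (see [read_xscale_lp_correlations()]).
#' @export
pairwise_cc_matrix <- function(datasets, laue, min_common = 20) {
  n <- length(datasets)
  if (n < 2) stop("need at least two datasets")
  ids <- vapply(datasets, function(d) d$dataset_id, character(1))
  merged <- lapply(datasets, function(d)
    .orbit_means(group_equivalents(d$reflections, laue)))
  cc <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  ncom <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(cc) <- 1
  for (i in seq_len(n)) ncom[i, i] <- length(merged[[i]]$key)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    mi <- merged[[i]]; mj <- merged[[j]]
    idx <- match(mi$key, mj$key)
    ok <- !is.na(idx)
    ncom[i, j] <- ncom[j, i] <- sum(ok)
    if (sum(ok) >= min_common) {
      r <- suppressWarnings(stats::cor(mi$mean[ok], mj$mean[idx[ok]]))
      cc[i, j] <- cc[j, i] <- r
    }
  }
  structure(list(ids = ids, cc = cc, n_common = ncom),
            class = "correlation_table")
}

#' Cluster datasets by intensity correlation
#'
#' Converts a correlation table to distances `d = sqrt(1 - cc^2)` (CC clamped
#' to `[0, 1]`; missing pairs imputed to the maximum distance 1), performs
#' average-linkage clustering, cuts at the threshold and names groups
#' `disX-clsY` (largest first).
#'
#' @param table A `correlation_table`.
#' @param threshold Cut height.
#' @param method Linkage (default `"average"`).
#' @return A `cluster_result`.
#' @export
cc_cluster <- function(table, threshold, method = "average") {
  cc <- pmin(pmax(table$cc, 0), 1)
  d <- sqrt(1 - cc^2)
  d[is.na(d)] <- 1
  diag(d) <- 0
  d <- (d + t(d)) / 2
  hc <- stats::hclust(stats::as.dist(d), method = method)
  .cut_and_name(hc, table$ids, threshold)
}

#' Dendrogram plot of a cluster result
#'
#' @param x A `cluster_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cluster_result <- function(x, ...) {
  graphics::plot(x$hclust, hang = -1,
                 xlab = "dataset", sub = "", ...)
  graphics::abline(h = x$threshold, lty = 2, col = "red3")
  invisible(x)
}
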