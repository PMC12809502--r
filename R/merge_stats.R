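# Quality indicators computed from unmerged reflection data: Rint/Rmeas,
# half-set CC1/2, the ISa error model, completeness, shell binning and the
# resolution-cutoff rule.

#' Group symmetry-equivalent observations
#'
#' Attaches to every observation the canonical asymmetric-unit key of its
#' symmetry orbit (Friedel mates included). All merging statistics consume
#' this grouping.
#'
#' @param reflections Data frame with columns `h,k,l,intensity,sigma` (and
#'   optionally `frame`, `dataset_id`).
#' @param laue A `laue_group` from [laue_operators()].
#' @return An object of class `refl_groups`: the reflection table plus the
#'   orbit `key` per observation, the canonical `asu` indices, and the Laue
#'   group. Observation order is preserved.
#' @export
group_equivalents <- function(reflections, laue) {
  hkl <- as.matrix(reflections[, c("h", "k", "l")])
  asu <- map_to_asu(hkl, laue)
  structure(list(reflections = reflections,
                 asu = asu,
                 key = .hkl_score(asu),
                 laue = laue),
            class = "refl_groups")
}

#' @export
print.refl_groups <- function(x, ...) {
  cat(sprintf("<refl_groups> %d observations, %d unique orbits, Laue %s\n",
              nrow(x$reflections), length(unique(x$key)), x$laue$name))
  invisible(x)
}

# per-orbit summaries used by several statistics
.group_table <- function(groups) {
  key <- groups$key
  I <- groups$reflections$intensity
  uk <- sort(unique(key))
  g <- match(key, uk)
  n <- tabulate(g, nbins = length(uk))
  s <- rowsum(I, g, reorder = TRUE)[, 1]
  m <- s / n
  list(uk = uk, g = g, n = n, sum = s, mean = m)
}

#' Internal merging R factors
#'
#' `r_int` is `sum |I - <I>| / sum I` over orbits with two or more
#' observations; `r_meas` is the redundancy-independent variant in which each
#' orbit's numerator is scaled by `sqrt(n/(n-1))`. Singleton orbits enter
#' neither sum.
#'
#' @param groups A `refl_groups` from [group_equivalents()].
#' @return A fraction, or `NA` when no orbit is multiply observed.
#' @export
r_int <- function(groups) .r_factor(groups, meas = FALSE)

#' @rdname r_int
#' @export
r_meas <- function(groups) .r_factor(groups, meas = TRUE)

.r_factor <- function(groups, meas) {
  gt <- .group_table(groups)
  multi <- gt$n >= 2
  if (!any(multi)) return(NA_real_)
  I <- groups$reflections$intensity
  dev <- abs(I - gt$mean[gt$g])
  num_per_group <- rowsum(dev, gt$g, reorder = TRUE)[, 1]
  if (meas)
    num_per_group <- num_per_group * sqrt(gt$n / pmax(gt$n - 1, 1))
  denom <- sum(gt$sum[multi])
  sum(num_per_group[multi]) / denom
}

#' Half-dataset correlation CC1/2
#'
#' Observations of each multiply-observed orbit are split into two random
#' halves (an odd observation goes to a random half); CC1/2 is the Pearson
#' correlation between the two half-mean vectors, in percent. Significance is
#' a one-sided test of CC > 0 at `alpha` with n-2 degrees of freedom.
#'
#' @param groups A `refl_groups`.
#' @param seed Integer seed of the random split (fixed default so batch
#'   reports are reproducible; reported in the result).
#' @param alpha Significance level of the one-sided test (default 0.01).
#' @return List with `cc` (percent), `significant` (flag), `n_groups`,
#'   `p_value` and `seed`; `cc` is `NA` with fewer than 3 qualifying orbits.
#' @export
cc_half <- function(groups, seed = 42L, alpha = 0.01) {
  gt <- .group_table(groups)
  multi <- which(gt$n >= 2)
  if (length(multi) < 3)
    return(list(cc = NA_real_, significant = FALSE,
                n_groups = length(multi), p_value = NA_real_, seed = seed))
  keep <- gt$g %in% multi
  I <- groups$reflections$intensity[keep]
  g <- match(gt$g[keep], multi)
  n <- gt$n[multi]

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  ord <- order(g, stats::runif(length(g)))
  pos <- sequence(n)                       # position within orbit after shuffle
  extra_to_first <- stats::rbinom(length(n), 1, 0.5)
  n1 <- n %/% 2 + (n %% 2) * extra_to_first
  first_half <- pos <= n1[g[ord]]
  Iord <- I[ord]; gord <- g[ord]
  # every orbit has >= 1 observation in each half (n >= 2), so both rowsum
  # results cover all orbits in ascending order
  m1 <- rowsum(Iord[first_half], gord[first_half], reorder = TRUE)[, 1] /
    tabulate(gord[first_half], nbins = length(n))
  m2 <- rowsum(Iord[!first_half], gord[!first_half], reorder = TRUE)[, 1] /
    tabulate(gord[!first_half], nbins = length(n))
  r <- suppressWarnings(stats::cor(m1, m2))
  if (is.na(r))
    return(list(cc = NA_real_, significant = FALSE,
                n_groups = length(multi), p_value = NA_real_, seed = seed))
  nn <- length(m1)
  tt <- r * sqrt((nn - 2) / max(1 - r^2, 1e-12))
  p <- stats::pt(tt, df = nn - 2, lower.tail = FALSE)
  list(cc = 100 * r, significant = is.finite(p) && p < alpha,
       n_groups = nn, p_value = p, seed = seed)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fit the two-parameter intensity error model (ISa)
#'
#' Fits `var(I_equivalents) = a * (sigma^2 + b * <I>^2)` across intensity
#' bins by least squares on the binned sample variances, and derives the
#' asymptotic signal-to-noise ISa = `1/sqrt(a*b)`: the I/sigma a very strong
#' reflection would reach under the fitted error model.
#'
#' @param groups A `refl_groups` with at least 10 multiply-observed orbits.
#' @param n_bins Number of equal-count intensity bins (default 10).
#' @return An object of class `error_model`: list with `a`, `b`, `isa`,
#'   `n_groups` and `diagnostic` (non-`NULL` when the fit degenerates, in
#'   which case `isa` is `NA`).
#' @references Diederichs, K. (2010). Acta Cryst. D66, 733-740.
#' @export
fit_error_model <- function(groups, n_bins = 10) {
  gt <- .group_table(groups)
  multi <- which(gt$n >= 2)
  fail <- function(msg) structure(
    list(a = NA_real_, b = NA_real_, isa = NA_real_,
         n_groups = length(multi), diagnostic = msg),
    class = "error_model")
  if (length(multi) < 10)
    return(fail("fewer than 10 multiply-observed orbits"))
  keep <- gt$g %in% multi
  g <- match(gt$g[keep], multi)
  I <- groups$reflections$intensity[keep]
  sg2 <- groups$reflections$sigma[keep]^2
  n <- gt$n[multi]
  m <- rowsum(I, g, reorder = TRUE)[, 1] / n
  ssq <- rowsum(I^2, g, reorder = TRUE)[, 1]
  s2 <- (ssq - n * m^2) / (n - 1)          # sample variance per orbit
  msig2 <- rowsum(sg2, g, reorder = TRUE)[, 1] / n

  m2u <- pmax(m^2 - s2 / n, 0)             # unbiased estimate of <I>_true^2
  nb <- min(n_bins, max(1, length(m) %/% 5))
  bin <- ceiling(rank(m, ties.method = "first") / (length(m) / nb))
  x1 <- tapply(msig2, bin, mean)
  x2 <- tapply(m2u, bin, mean)
  y  <- tapply(s2, bin, mean)
  X <- cbind(x1, x2)
  # least squares on the binned variances; bins are reweighted by the
  # sampling variance of a mean of chi-square variates, var(s2) =
  # 2 sigma'^4/(n-1), so the strong-intensity bins do not dominate the fit
  y <- as.vector(y)
  fit_once <- function(w) tryCatch(
    stats::coef(stats::lm.wfit(X, as.vector(y), as.vector(w))),
    error = function(e) c(NA, NA))
  cf <- fit_once(rep(1, nb))
  valid <- !anyNA(cf) && all(cf > 0)
  if (anyNA(cf)) cf <- c(1, 1e-4)
  cf <- pmax(cf, c(1e-6, 1e-12))   # recoverable start for the reweighting
  for (it in 1:6) {
    pred <- cf[1] * msig2 + cf[2] * m2u
    v_orbit <- 2 * pmax(pred, 1e-12)^2 / pmax(n - 1, 1)
    nbin <- tabulate(as.integer(bin), nbins = nb)
    wbin <- nbin^2 / pmax(as.vector(tapply(v_orbit, bin, sum)), 1e-300)
    cf_new <- fit_once(wbin)
    if (anyNA(cf_new) || any(cf_new <= 0)) break
    done <- max(abs(cf_new - cf) / pmax(abs(cf), 1e-12)) < 1e-8
    cf <- cf_new
    valid <- TRUE
    if (done) break
  }
  if (!valid || anyNA(cf) || cf[1] <= 0 || cf[2] <= 0) {
    # retry with non-negativity enforced before declaring the fit degenerate
    cf <- c(NA_real_, NA_real_)
    obj <- function(p) sum((y - X %*% exp(p))^2)
    op <- tryCatch(stats::optim(c(0, log(1e-4)), obj), error = function(e) NULL)
    if (!is.null(op) && op$value < 0.99 * sum((y - mean(y))^2))
      cf <- exp(op$par)
  }
  a <- unname(cf[1]); ab <- unname(cf[2])
  if (!is.finite(a) || !is.finite(ab) || a <= 1e-12 || ab <= 1e-18)
    return(fail("degenerate fit: non-positive error-model parameters"))
  structure(list(a = a, b = ab / a, isa = 1 / sqrt(ab),
                 n_groups = length(multi), diagnostic = NULL),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  if (is.na(x$isa))
    cat("<error_model> degenerate:", x$diagnostic, "\n")
  else
    cat(sprintf("<error_model> a=%.4g b=%.4g ISa=%.2f (%d orbits)\n",
                x$a, x$b, x$isa, x$n_groups))
  invisible(x)
}

#' Completeness of a reflection set
#'
#' Percentage of the theoretically measurable unique reflections (given
#' cell, Laue symmetry, centering and resolution window) actually observed.
#'
#' @param groups A `refl_groups`.
#' @param cell A [unit_cell()].
#' @param d_max,d_min Resolution window in Angstrom.
#' @return Percent in `[0, 100]`.
#' @export
completeness <- function(groups, cell, d_max, d_min) {
  theo <- count_theoretical_unique(cell, groups$laue, d_max, d_min)
  if (theo == 0) stop("no theoretical reflections in the window")
  d <- d_spacing(as.matrix(groups$reflections[, c("h", "k", "l")]), cell)
  inw <- d >= d_min & d <= d_max
  obs <- length(unique(groups$key[inw]))
  100 * obs / theo
}

#' Per-shell merging statistics
#'
#' Bins reflections into shells of equal reciprocal volume (linear in
#' 1/d^3) between the data's own resolution limits and computes every
#' indicator per shell, appending an overall row.
#'
#' @param reflections Data frame of unmerged observations.
#' @param cell A [unit_cell()].
#' @param laue A `laue_group`.
#' @param n_shells Number of shells (default 10).
#' @param seed Seed forwarded to [cc_half()].
#' @return A data frame of class `shell_stats`; last row is the overall set.
#' @export
bin_shells <- function(reflections, cell, laue, n_shells = 10, seed = 42L) {
  if (n_shells < 1) stop("n_shells must be >= 1")
  d <- d_spacing(as.matrix(reflections[, c("h", "k", "l")]), cell)
  d_lo <- max(d); d_hi <- min(d)
  s3 <- 1 / d^3
  breaks <- seq(1 / d_lo^3, 1 / d_hi^3, length.out = n_shells + 1)
  shell <- pmin(pmax(findInterval(s3, breaks, rightmost.closed = TRUE), 1),
                n_shells)
  rows <- lapply(seq_len(n_shells), function(i) {
    sub <- reflections[shell == i, , drop = FALSE]
    .shell_row(sub, cell, laue,
               d_max = breaks[i]^(-1 / 3), d_min = breaks[i + 1]^(-1 / 3),
               seed = seed)
  })
  overall <- .shell_row(reflections, cell, laue, d_max = d_lo, d_min = d_hi,
                        seed = seed)
  out <- do.call(rbind, c(rows, list(overall)))
  out$shell <- c(seq_len(n_shells), NA)
  rownames(out) <- c(sprintf("shell_%d", seq_len(n_shells)), "overall")
  class(out) <- c("shell_stats", "data.frame")
  out
}

.shell_row <- function(sub, cell, laue, d_max, d_min, seed) {
  if (nrow(sub) == 0)
    return(data.frame(d_max = d_max, d_min = d_min, n_obs = 0L, n_unique = 0L,
                      multiplicity = NA_real_, completeness = NA_real_,
                      r_int = NA_real_, r_meas = NA_real_, cc_half = NA_real_,
                      cc_significant = FALSE, mean_i_over_sigma = NA_real_))
  gr <- group_equivalents(sub, laue)
  nu <- length(unique(gr$key))
  cc <- cc_half(gr, seed = seed)
  comp <- tryCatch(completeness(gr, cell, d_max = d_max, d_min = d_min),
                   error = function(e) NA_real_)
  data.frame(d_max = d_max, d_min = d_min,
             n_obs = nrow(sub), n_unique = nu,
             multiplicity = nrow(sub) / nu,
             completeness = comp,
             r_int = r_int(gr), r_meas = r_meas(gr),
             cc_half = cc$cc, cc_significant = cc$significant,
             mean_i_over_sigma = mean(sub$intensity / sub$sigma))
}

#' Resolution cutoff from shell statistics
#'
#' Scans shells from low to high resolution; a shell passes while CC1/2 is
#' defined, at or above `cc_half_min` and statistically significant, mean
#' I/sigma is at least `i_sig_min`, and Rint is defined. The first failing
#' shell terminates the scan and the cutoff is the `d_min` of the last
#' passing shell. If every shell passes the data's own `d_min` is returned;
#' if the first shell already fails, the innermost `d_max` is returned with a
#' warning.
#'
#' @param shells A `shell_stats` table from [bin_shells()] (the overall row,
#'   if present, is ignored).
#' @param cc_half_min CC1/2 threshold in percent (default 30).
#' @param i_sig_min Mean I/sigma threshold (default 1).
#' @return Resolution cutoff in Angstrom.
#' @export
estimate_resolution <- function(shells, cc_half_min = 30, i_sig_min = 1) {
  sh <- if (!is.null(shells$shell))
    shells[!is.na(shells$shell), , drop = FALSE] else shells
  if (nrow(sh) < 1) stop("no shells to scan")
  sh <- sh[order(-sh$d_max), , drop = FALSE]
  pass <- with(sh, !is.na(cc_half) & cc_half >= cc_half_min & cc_significant &
                 !is.na(mean_i_over_sigma) & mean_i_over_sigma >= i_sig_min &
                 !is.na(r_int))
  if (!pass[1]) {
    warning("first resolution shell fails the cutoff rule; returning innermost d_max")
    return(sh$d_max[1])
  }
  last_pass <- which(!pass)[1]
  if (is.na(last_pass)) return(sh$d_min[nrow(sh)])   # all shells pass
  sh$d_min[last_pass - 1]
}

#' Summary indicators of one dataset
#'
#' Populates the per-dataset row of the batch summary table: cell, volume,
#' ISa, Rmeas, CC1/2, completeness and the resolution estimate. Individual
#' indicator failures are recorded as `NA` fields; the row is always
#' produced.
#'
#' @param record An [ed_dataset()].
#' @param laue A `laue_group`; defaults to the Laue class of the header's
#'   space-group number.
#' @param n_shells Shell count for the resolution estimate.
#' @param seed Seed forwarded to [cc_half()].
#' @return A one-row data frame with the canonical summary columns.
#' @export
dataset_summary <- function(record, laue = NULL, n_shells = 10, seed = 42L) {
  hd <- record$header
  if (is.null(laue)) laue <- laue_for_spacegroup(hd$space_group_number)
  uc <- hd$unit_cell
  refl <- record$reflections
  try_na <- function(expr) tryCatch(suppressWarnings(expr),
                                    error = function(e) NA_real_)
  gr <- group_equivalents(refl, laue)
  d <- d_spacing(as.matrix(refl[, c("h", "k", "l")]), uc)
  em <- fit_error_model(gr)
  cc <- cc_half(gr, seed = seed)
  shells <- tryCatch(bin_shells(refl, uc, laue, n_shells = n_shells, seed = seed),
                     error = function(e) NULL)
  reso <- if (is.null(shells)) NA_real_ else
    try_na(suppressWarnings(estimate_resolution(shells)))
  data.frame(
    dataset_id = record$dataset_id,
    space_group_number = hd$space_group_number,
    a = uc[["a"]], b = uc[["b"]], c = uc[["c"]],
    alpha = uc[["alpha"]], beta = uc[["beta"]], gamma = uc[["gamma"]],
    volume = cell_volume(uc),
    isa = em$isa,
    r_meas = try_na(r_meas(gr)),
    cc_half = cc$cc,
    completeness = if (nrow(refl))
      try_na(completeness(gr, uc, d_max = max(d), d_min = min(d))) else NA_real_,
    resolution_estimate = reso,
    stringsAsFactors = FALSE)
}
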