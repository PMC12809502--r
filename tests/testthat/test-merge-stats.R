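lg1 <- laue_operators("-1")

test_that("equivalent grouping collapses Friedel mates and distinct orbits", {
  refl <- fx_refl(rbind(c(1, 2, 3), c(-1, -2, -3), c(2, 0, 0)), c(10, 12, 5))
  gr <- group_equivalents(refl, lg1)
  expect_identical(length(unique(gr$key)), 2L)
  # order preserved
  expect_identical(gr$reflections$intensity, c(10, 12, 5))
  # symmetry-distinct observations give singleton orbits
  refl2 <- fx_refl(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), c(1, 2, 3))
  expect_identical(length(unique(group_equivalents(refl2, lg1)$key)), 3L)
})

test_that("orbit count under mmm equals the brute-force orbit count", {
  set.seed(3)
  lg <- laue_operators("mmm")
  hkl <- matrix(sample(-5:5, 300, replace = TRUE), ncol = 3)
  hkl <- hkl[rowSums(abs(hkl)) > 0, , drop = FALSE]
  gr <- group_equivalents(fx_refl(hkl, rexp(nrow(hkl))), lg)
  brute <- unique(t(apply(hkl, 1, function(h) {
    imgs <- t(vapply(lg$operators, function(m) drop(m %*% h), numeric(3)))
    imgs[order(imgs[, 1], imgs[, 2], imgs[, 3]), ][1, ]
  })))
  expect_identical(length(unique(gr$key)), nrow(brute))
})

test_that("Rint and Rmeas match hand evaluation and the brute-force oracle", {
  gr <- group_equivalents(fx_refl(rbind(c(1, 2, 3), c(1, 2, 3)), c(10, 12)), lg1)
  expect_equal(r_int(gr), 2 / 22, tolerance = 1e-14)
  expect_equal(r_meas(gr), sqrt(2) * 2 / 22, tolerance = 1e-14)
  # identical equivalents give zero
  gr0 <- group_equivalents(fx_refl(rbind(c(1, 2, 3), c(1, 2, 3)), c(7, 7)), lg1)
  expect_identical(r_int(gr0), 0)
  expect_identical(r_meas(gr0), 0)
  # singletons only -> undefined, not zero
  grs <- group_equivalents(fx_refl(rbind(c(1, 0, 0), c(0, 1, 0)), c(1, 2)), lg1)
  expect_true(is.na(r_int(grs)))
  # random groups vs independent brute force
  set.seed(11)
  for (rep in 1:20) {
    sizes <- sample(1:5, 30, replace = TRUE)
    I <- abs(rnorm(sum(sizes), 100, 30))
    hkl <- cbind(rep(seq_along(sizes), sizes), 1, 2)
    gr <- group_equivalents(fx_refl(hkl, I), lg1)
    oracle <- brute_r_factors(split(I, rep(seq_along(sizes), sizes)))
    expect_equal(r_int(gr), unname(oracle["r_int"]), tolerance = 1e-12)
    expect_equal(r_meas(gr), unname(oracle["r_meas"]), tolerance = 1e-12)
  }
})

test_that("per-group Rmeas/Rint ratio is sqrt(n/(n-1))", {
  set.seed(2)
  for (n in 2:6) {
    gr <- group_equivalents(fx_refl(matrix(rep(c(1, 2, 3), n), ncol = 3,
                                           byrow = TRUE),
                                    abs(rnorm(n, 50, 10))), lg1)
    expect_equal(r_meas(gr) / r_int(gr), sqrt(n / (n - 1)), tolerance = 1e-12)
  }
})

test_that("CC1/2 is 100 for identical duplicates and NA when underpowered", {
  set.seed(4)
  n <- 200
  I <- rexp(n, 1 / 100)
  gr <- group_equivalents(fx_refl(cbind(seq_len(n), 1, 2)[rep(1:n, each = 2), ],
                                  rep(I, each = 2)), lg1)
  cc <- cc_half(gr)
  expect_equal(cc$cc, 100)
  expect_true(cc$significant)
  small <- group_equivalents(fx_refl(rbind(c(1, 1, 2), c(1, 1, 2)), c(1, 2)), lg1)
  expect_true(is.na(cc_half(small)$cc))
})

test_that("CC1/2 is invariant under global intensity scaling", {
  ds <- fx_wedge_dataset()$record
  gr <- group_equivalents(ds$reflections, lg1)
  r2 <- ds$reflections
  r2$intensity <- r2$intensity * 1e3
  gr2 <- group_equivalents(r2, lg1)
  expect_equal(cc_half(gr, seed = 7)$cc, cc_half(gr2, seed = 7)$cc,
               tolerance = 1e-9)
})

test_that("CC1/2 matches the analytic expectation for planted variances", {
  # groups of two observations; signal variance ss2, per-half noise sn2
  set.seed(5)
  n <- 500; ss2 <- 100; sn2 <- 50
  mu <- rnorm(n, 50, sqrt(ss2))
  ss2_real <- stats::var(mu)          # conditional expectation uses the draw
  ccs <- vapply(1:60, function(s) {
    I <- rep(mu, each = 2) + rnorm(2 * n, 0, sqrt(sn2))
    gr <- group_equivalents(fx_refl(cbind(seq_len(n), 1, 2)[rep(1:n, each = 2), ], I),
                            lg1)
    cc_half(gr, seed = s)$cc
  }, numeric(1))
  expected <- 100 * ss2_real / (ss2_real + sn2)
  expect_lt(abs(mean(ccs) - expected), 3 * stats::sd(ccs) / sqrt(length(ccs)) + 1)
})

test_that("error-model fit recovers planted parameters and flags degeneracy", {
  ds <- fx_full_dataset()$record     # planted a=1, b=1e-4 -> ISa 100
  em <- fit_error_model(group_equivalents(ds$reflections, lg1))
  expect_lt(abs(em$isa - 100) / 100, 0.1)
  # degenerate: noise-free equivalents
  refl <- fx_refl(cbind(rep(1:40, each = 3), 1, 2),
                  rep(rexp(40, 0.01), each = 3))
  em0 <- fit_error_model(group_equivalents(refl, lg1))
  expect_true(is.na(em0$isa))
  expect_match(em0$diagnostic, "degenerate")
  # too few orbits
  em2 <- fit_error_model(group_equivalents(fx_refl(rbind(c(1, 1, 1), c(1, 1, 1)),
                                                   c(1, 2)), lg1))
  expect_true(is.na(em2$isa))
})

test_that("completeness counts observed unique against the enumeration", {
  cell <- unit_cell(10, 10, 10)
  grid <- edbatch:::.enumerate_hkl(cell, 2.5, 20)
  reps <- map_to_asu(grid, lg1)
  uni <- unique(as.data.frame(reps))
  full <- group_equivalents(fx_refl(as.matrix(uni), rexp(nrow(uni))), lg1)
  expect_equal(completeness(full, cell, d_max = 20, d_min = 2.5), 100)
  half <- uni[seq_len(nrow(uni) %/% 2), ]
  ghalf <- group_equivalents(fx_refl(as.matrix(half), rexp(nrow(half))), lg1)
  expect_equal(ghalf |> completeness(cell, d_max = 20, d_min = 2.5),
               100 * (nrow(uni) %/% 2) / nrow(uni), tolerance = 1e-9)
})

test_that("shell binning is equal-volume with monotone boundaries", {
  ds <- fx_wedge_dataset()$record
  sh <- bin_shells(ds$reflections, ds$header$unit_cell, lg1, n_shells = 8)
  body <- sh[!is.na(sh$shell), ]
  expect_identical(nrow(body), 8L)
  expect_true(all(diff(body$d_max) < 0))
  expect_true(all(body$d_max > body$d_min))
  # adjacent shells share boundaries
  expect_equal(body$d_min[-8], body$d_max[-1], tolerance = 1e-9)
  # one shell reproduces the overall row
  sh1 <- bin_shells(ds$reflections, ds$header$unit_cell, lg1, n_shells = 1)
  expect_equal(sh1$r_meas[1], sh1$r_meas[2])
  expect_equal(sh1$n_obs[1], sh1$n_obs[2])
  # equal reciprocal volume -> comparable counts for uniform-in-volume data
  set.seed(6)
  counts <- body$n_obs
  expect_lt(max(counts) / min(counts), 2.5)
})

test_that("the resolution rule applies thresholds shell by shell", {
  mk <- function(cc, isig = rep(5, length(cc)), sig = rep(TRUE, length(cc))) {
    n <- length(cc)
    d_max <- seq(10, 2, length.out = n + 1)[-(n + 1)]
    d_min <- seq(10, 2, length.out = n + 1)[-1]
    data.frame(shell = seq_len(n), d_max = d_max, d_min = d_min,
               cc_half = cc, cc_significant = sig,
               mean_i_over_sigma = isig, r_int = 0.1)
  }
  sh <- mk(c(99, 95, 60, 20, 5))
  expect_equal(estimate_resolution(sh), sh$d_min[3])
  # all pass -> data's own d_min
  expect_equal(estimate_resolution(mk(c(99, 95, 60))), 2)
  # first shell fails -> innermost d_max with warning
  expect_warning(out <- estimate_resolution(mk(c(10, 99, 99))), "first")
  expect_equal(out, 10)
  # I/sigma gate can terminate the scan too
  sh2 <- mk(c(99, 95, 90, 80), isig = c(9, 4, 0.5, 3))
  expect_equal(estimate_resolution(sh2), sh2$d_min[2])
  # monotonicity in the CC1/2 threshold
  sh3 <- mk(c(99, 80, 55, 35, 20, 8))
  cuts <- vapply(c(10, 30, 50, 70, 90),
                 function(th) estimate_resolution(sh3, cc_half_min = th),
                 numeric(1))
  expect_true(all(diff(cuts) >= -1e-12))
})

test_that("dataset_summary fills every field and survives partial failure", {
  row <- dataset_summary(fx_wedge_dataset()$record, lg1)
  expect_identical(names(row), edbatch:::.summary_cols)
  expect_false(anyNA(row))
  # a dataset too small for CC1/2 still yields a row
  tiny <- fx_record(fx_refl(rbind(c(1, 2, 3), c(1, 2, 3)), c(5, 6)))
  row2 <- dataset_summary(tiny, lg1)
  expect_true(is.na(row2$cc_half))
  expect_true(is.na(row2$isa))
  expect_false(is.na(row2$r_meas))
})

test_that("disjoint-index unions add observation and unique counts", {
  a <- fx_refl(cbind(1:50, 1, 2), rexp(50))
  b <- fx_refl(cbind(1:40, 2, 3), rexp(40))
  ga <- group_equivalents(a, lg1)
  gb <- group_equivalents(b, lg1)
  gu <- group_equivalents(rbind(a, b), lg1)
  expect_identical(length(unique(gu$key)),
                   length(unique(ga$key)) + length(unique(gb$key)))
  expect_identical(nrow(gu$reflections), nrow(a) + nrow(b))
})
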