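lg1 <- laue_operators("-1")

test_that("threshold filtering picks and rejects with reasons", {
  rows <- data.frame(
    dataset_id = c("exp10", "lowisa", "lowcc", "missing"),
    isa = c(7.51, 4.2, 9, NA),
    cc_half = c(98.18, 97, 80, 96),
    completeness = c(87.61, 85, 90, 88))
  flt <- filter_datasets(rows, filter_thresholds())
  expect_identical(flt$picked, "exp10")
  expect_match(flt$reasons[["lowisa"]], "ISa<5")
  expect_match(flt$reasons[["lowcc"]], "CC1/2<95")
  expect_match(flt$reasons[["missing"]], "ISa missing")
  # all-zero thresholds pick everything
  flt0 <- filter_datasets(rows, filter_thresholds(0, 0, 0))
  expect_identical(flt0$picked, rows$dataset_id)
  # realtime profile ignores completeness
  rt <- filter_datasets(data.frame(dataset_id = "w", isa = 6, cc_half = 92,
                                   completeness = 10),
                        realtime_thresholds())
  expect_identical(rt$picked, "w")
})

make_scaled_set <- function(ks = c(0.5, 1, 2), bs = c(0, 0, 0),
                            noise = c(a = 1, b = 1e-4), seed = 20) {
  tr <- fx_memo("truth_scale", function()
    make_ground_truth(unit_cell(12, 14, 16, 85, 95, 100),
                      laue_operators("-1"), 1.2, seed = 5))
  lapply(seq_along(ks), function(i)
    make_dataset(tr, wedge_spec(phi_start = (i - 1) * 50,
                                phi_end = (i - 1) * 50 + 120,
                                oscillation = 0.5, scale = ks[i],
                                b_factor = bs[i],
                                orientation = c(0.3 * i, 0.7, 1.1 * i),
                                error_model = noise,
                                sigma_floor = 0.5, sigma_frac = 0.02),
                 seed = seed + i, dataset_id = paste0("d", i))$record)
}

test_that("identical datasets scale to unity", {
  ds <- fx_wedge_dataset()$record
  d2 <- ds; d2$dataset_id <- "copy"
  d2$reflections$dataset_id <- "copy"
  sol <- fit_scales(list(ds, d2), lg1)
  expect_equal(unname(sol$k), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(sol$b), c(0, 0))
})

test_that("planted scales are recovered within 2% (noise) and 1e-6 (noise-free)", {
  ks <- c(0.5, 1, 2)
  gauged <- ks / exp(mean(log(ks)))
  sol <- fit_scales(make_scaled_set(ks), lg1)
  expect_lt(max(abs(sol$k - gauged) / gauged), 0.02)
  sol0 <- fit_scales(make_scaled_set(ks, noise = c(a = 1e-12, b = 1e-18)), lg1)
  expect_lt(max(abs(sol0$k - gauged)), 1e-5)
})

test_that("a planted B-factor difference is recovered within 10%", {
  bs <- c(0, 5, 2.5)
  sol <- fit_scales(make_scaled_set(ks = c(1, 1, 1), bs = bs), lg1,
                    with_b = TRUE)
  db_true <- bs[2] - bs[1]
  db_fit <- sol$b[[2]] - sol$b[[1]]
  expect_lt(abs(db_fit - db_true) / db_true, 0.1)
})

test_that("disconnected dataset graphs are refused with component names", {
  a <- fx_record(fx_refl(cbind(1:40, 1, 2), rexp(40)), id = "left")
  b <- fx_record(fx_refl(cbind(1:40, 3, 4), rexp(40)), id = "right")
  expect_error(fit_scales(list(a, b), lg1), "left")
  expect_error(fit_scales(list(a, b), lg1), "not connected")
})

test_that("planted outlier frames are excluded exactly", {
  tr <- fx_memo("truth_scale", function()
    make_ground_truth(unit_cell(12, 14, 16, 85, 95, 100),
                      laue_operators("-1"), 1.2, seed = 5))
  w <- wedge_spec(phi_start = 0, phi_end = 60, oscillation = 0.5,
                  outlier_frames = c(40, 41, 42),
                  error_model = c(a = 1, b = 1e-4),
                  sigma_floor = 0.5, sigma_frac = 0.02)
  for (seed in c(9, 17)) {
    ds <- make_dataset(tr, w, seed = seed)
    ex <- exclude_outlier_frames(ds$record, lg1)
    expect_identical(nrow(ex), 1L)
    expect_identical(c(ex$from, ex$to), c(40L, 42L))
  }
})

test_that("smooth decay and clean data yield zero exclusions", {
  tr <- fx_memo("truth_scale", function()
    make_ground_truth(unit_cell(12, 14, 16, 85, 95, 100),
                      laue_operators("-1"), 1.2, seed = 5))
  decay <- make_dataset(tr, wedge_spec(phi_end = 60, oscillation = 0.5,
                                       dose_decay = 0.01,
                                       error_model = c(a = 1, b = 1e-4)),
                        seed = 9)
  expect_identical(nrow(exclude_outlier_frames(decay$record, lg1)), 0L)
  clean <- make_dataset(tr, wedge_spec(phi_end = 60, oscillation = 0.5),
                        seed = 9)
  expect_identical(nrow(exclude_outlier_frames(clean$record, lg1)), 0L)
})

test_that("frameless datasets are a warned no-op", {
  refl <- fx_refl(cbind(rep(1:30, each = 2), 1, 2), rexp(60))
  refl$frame <- NULL
  rec <- fx_record(refl)
  expect_warning(ex <- exclude_outlier_frames(rec, lg1), "frameless")
  expect_identical(nrow(ex), 0L)
})

test_that("unit-scale merging reproduces plain group means", {
  ds <- fx_wedge_dataset()$record
  mg <- merge_datasets(list(ds), NULL, lg1)
  gr <- group_equivalents(ds$reflections, lg1)
  gt <- edbatch:::.group_table(gr)
  w <- 1 / ds$reflections$sigma^2
  wm <- rowsum(w * ds$reflections$intensity, gt$g)[, 1] / rowsum(w, gt$g)[, 1]
  got <- mg$merged$reflections$intensity
  expect_equal(sort(got), sort(unname(wm)), tolerance = 1e-9)
  expect_true(mg$merged$merged)
})

test_that("merging two half wedges beats either input's completeness", {
  tr <- fx_truth_p1()
  cell <- fx_triclinic_cell()
  w1 <- make_dataset(tr, wedge_spec(phi_end = 40, oscillation = 0.5,
                                    error_model = c(a = 1, b = 1e-4)),
                     seed = 31, dataset_id = "w1")$record
  w2 <- make_dataset(tr, wedge_spec(phi_start = 120, phi_end = 160,
                                    oscillation = 0.5,
                                    orientation = c(1.2, 0.8, 0.3),
                                    error_model = c(a = 1, b = 1e-4)),
                     seed = 32, dataset_id = "w2")$record
  comp <- function(refl) completeness(group_equivalents(refl, lg1), cell,
                                      d_max = 25, d_min = 1.5)
  merged <- merge_datasets(list(w1, w2), fit_scales(list(w1, w2), lg1), lg1)
  cm <- comp(merged$merged$reflections)
  expect_gt(cm, comp(w1$reflections))
  expect_gt(cm, comp(w2$reflections))
})

test_that("merge output is invariant under dataset order", {
  set <- make_scaled_set()
  sol <- fit_scales(set, lg1)
  m1 <- merge_datasets(set, sol, lg1)
  m2 <- merge_datasets(rev(set), sol, lg1)
  o1 <- m1$merged$reflections[order(m1$merged$reflections$h,
                                    m1$merged$reflections$k,
                                    m1$merged$reflections$l), ]
  o2 <- m2$merged$reflections[order(m2$merged$reflections$h,
                                    m2$merged$reflections$k,
                                    m2$merged$reflections$l), ]
  expect_equal(o1$intensity, o2$intensity, tolerance = 1e-12)
})

test_that("global intensity scaling propagates through merging untouched", {
  set <- make_scaled_set()
  scaled <- lapply(set, function(d) {
    d$reflections$intensity <- d$reflections$intensity * 7
    d$reflections$sigma <- d$reflections$sigma * 7
    d
  })
  lgx <- lg1
  m1 <- merge_datasets(set, fit_scales(set, lgx), lgx, seed = 3)
  m2 <- merge_datasets(scaled, fit_scales(scaled, lgx), lgx, seed = 3)
  expect_equal(m2$merged$reflections$intensity,
               7 * m1$merged$reflections$intensity, tolerance = 1e-6)
  ov1 <- m1$shells[is.na(m1$shells$shell), ]
  ov2 <- m2$shells[is.na(m2$shells$shell), ]
  expect_equal(ov1$r_meas, ov2$r_meas, tolerance = 1e-9)
  expect_equal(ov1$cc_half, ov2$cc_half, tolerance = 1e-6)
})

test_that("excluded frames are dropped from the merged set", {
  ds <- fx_wedge_dataset()$record
  ex <- list(wedge1 = data.frame(from = 1L, to = 20L))
  mg <- merge_datasets(list(ds), NULL, lg1, excluded = ex)
  kept <- ds$reflections$frame >= 20
  expect_lte(mg$n_obs_used, sum(ds$reflections$frame >= 19))
  expect_lt(mg$n_obs_used, nrow(ds$reflections))
})
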