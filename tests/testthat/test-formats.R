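test_that("XDS_ASCII files round-trip through write and read", {
  ds <- fx_wedge_dataset()$record
  f <- withr::local_tempfile(fileext = ".HKL")
  write_xds_ascii(ds, f)
  back <- read_xds_ascii(f)
  expect_equal(back$reflections$h, ds$reflections$h)
  expect_equal(back$reflections$intensity, ds$reflections$intensity,
               tolerance = 1e-6)
  expect_equal(back$reflections$frame, ds$reflections$frame, tolerance = 1e-3)
  expect_equal(unclass(back$header$unit_cell), unclass(ds$header$unit_cell),
               tolerance = 1e-4)
  expect_identical(back$dataset_id, ds$dataset_id)
  # second write is byte-identical
  f2 <- withr::local_tempfile(fileext = ".HKL")
  write_xds_ascii(back, f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("column mapping follows the ITEM_ declarations, not position", {
  f <- withr::local_tempfile(fileext = ".HKL")
  writeLines(c("!FORMAT=XDS_ASCII",
               "!UNIT_CELL_CONSTANTS= 10 12 15 90 90 90",
               "!DATA_RANGE= 1 20",
               "!OSCILLATION_RANGE= 0.5",
               "!X-RAY_WAVELENGTH= 0.0251",
               "!ITEM_IOBS=1", "!ITEM_SIGMA(IOBS)=2", "!ITEM_ZD=3",
               "!ITEM_H=4", "!ITEM_K=5", "!ITEM_L=6",
               "!END_OF_HEADER",
               "100.0 5.0 10.2 1 2 3",
               "!END_OF_DATA"), f)
  ds <- read_xds_ascii(f)
  r <- ds$reflections
  expect_identical(c(r$h, r$k, r$l), c(1L, 2L, 3L))
  expect_equal(r$intensity, 100)
  expect_equal(r$sigma, 5)
  expect_equal(r$frame, 10.2)
})

test_that("missing declarations and invalid records are diagnosed", {
  f <- withr::local_tempfile(fileext = ".HKL")
  writeLines(c("!ITEM_H=1", "!ITEM_K=2", "!ITEM_L=3", "!END_OF_HEADER",
               "1 2 3", "!END_OF_DATA"), f)
  expect_error(read_xds_ascii(f), "ITEM_IOBS")
  writeLines(c("!ITEM_H=1", "!ITEM_K=2", "!ITEM_L=3", "!ITEM_IOBS=4",
               "!ITEM_SIGMA(IOBS)=5", "!END_OF_HEADER",
               "1 2 3 10 1", "1 2 3 xx 1", "!END_OF_DATA"), f)
  expect_error(read_xds_ascii(f), "line 8")
  writeLines(c("!ITEM_H=1", "!ITEM_K=2", "!ITEM_L=3", "!ITEM_IOBS=4",
               "!ITEM_SIGMA(IOBS)=5", "!END_OF_HEADER",
               "1 2 3 10 1", "2 2 3 10 0", "!END_OF_DATA"), f)
  expect_error(read_xds_ascii(f), "sigma.*row: 2")
})

test_that("empty datasets and unknown header keys round-trip", {
  hd <- list(unit_cell = fx_triclinic_cell(), space_group_number = 1L,
             wavelength = 0.0251, oscillation_per_frame = 0.5,
             frame_range = c(1L, 10L),
             extra = list(DETECTOR = "custom_cam", NOISE = "1.4"))
  ds <- ed_dataset(hd, empty_reflections(), dataset_id = "empty")
  f <- withr::local_tempfile(fileext = ".HKL")
  write_xds_ascii(ds, f)
  back <- read_xds_ascii(f)
  expect_identical(nrow(back$reflections), 0L)
  expect_identical(back$header$extra$DETECTOR, "custom_cam")
  expect_identical(back$header$extra$NOISE, "1.4")
})

test_that("merged output has one row per unique index and no frame column", {
  ds <- fx_wedge_dataset()$record
  lg <- laue_operators("-1")
  mg <- merge_datasets(list(ds), NULL, lg)$merged
  f <- withr::local_tempfile(fileext = ".HKL")
  write_xds_ascii(mg, f, merged = TRUE)
  back <- read_xds_ascii(f)
  expect_true(back$merged)
  key <- with(back$reflections, paste(h, k, l))
  expect_identical(anyDuplicated(key), 0L)
  expect_true(back$frameless)
  # duplicate rows refuse the merged flag
  dup <- fx_record(fx_refl(rbind(c(1, 2, 3), c(1, 2, 3)), c(5, 6)))
  expect_error(write_xds_ascii(dup, f, merged = TRUE), "one row per unique")
})

test_that("XSCALE.LP correlation blocks parse into symmetric tables", {
  f <- withr::local_tempfile(fileext = ".LP")
  writeLines(c(" INPUT_FILE= a.HKL", " INPUT_FILE= b.HKL", " INPUT_FILE= c.HKL",
               "",
               " CORRELATIONS BETWEEN INPUT DATA SETS AFTER CORRECTIONS",
               "",
               "    #i   #j   common  corr",
               "     1    2      500  0.920",
               "     1    3       40  0.150"), f)
  tab <- read_xscale_lp_correlations(f)
  expect_identical(dim(tab$cc), c(3L, 3L))
  expect_equal(tab$cc[1, 2], 0.92)
  expect_equal(tab$cc[2, 1], 0.92)
  expect_equal(tab$n_common[1, 3], 40)
  expect_true(is.na(tab$cc[2, 3]))    # absent pair flagged, not zero
  expect_equal(diag(tab$cc), rep(1, 3))
})

test_that("correlation-table corner cases are handled", {
  f <- withr::local_tempfile(fileext = ".LP")
  writeLines("no block here", f)
  expect_error(read_xscale_lp_correlations(f), "CORRELATIONS")
  writeLines(c(" INPUT_FILE= a.HKL",
               " CORRELATIONS BETWEEN INPUT DATA SETS"), f)
  tab <- read_xscale_lp_correlations(f)
  expect_identical(dim(tab$cc), c(1L, 1L))
  expect_equal(tab$cc[1, 1], 1)
  writeLines(c(" CORRELATIONS BETWEEN INPUT DATA SETS",
               "  1  2  100  0.5", "  1  2  100  0.7"), f)
  expect_error(read_xscale_lp_correlations(f), "\\(1,2\\)")
})

test_that("SMV images round-trip bit-exactly with headers preserved", {
  img <- make_beam_image(c(100.3, 120.9), seed = 5, size = 64)$image
  img$header[["DISTANCE"]] <- "958"
  img$header[["OSC_RANGE"]] <- "0.23"
  f <- withr::local_tempfile(fileext = ".img")
  write_smv(img, f)
  back <- read_smv(f)
  expect_identical(back$pixels, img$pixels)
  expect_identical(back$header[["DISTANCE"]], "958")
  expect_identical(back$header[["OSC_RANGE"]], "0.23")
  # zero image round-trip
  z <- list(header = c(PIXEL_SIZE = "0.055"),
            pixels = matrix(0L, 64, 64))
  write_smv(z, f)
  expect_identical(read_smv(f)$pixels, z$pixels)
})

test_that("SMV write clamps saturated pixels and read detects truncation", {
  px <- matrix(0L, 16, 16)
  px[5, 7] <- 70000L
  f <- withr::local_tempfile(fileext = ".img")
  expect_warning(write_smv(list(header = character(), pixels = px), f),
                 "clamped")
  expect_identical(read_smv(f)$pixels[5, 7], 65535L)
  # truncate the pixel block
  sz <- file.size(f)
  con <- file(f, "rb"); raw <- readBin(con, "raw", sz - 100); close(con)
  con <- file(f, "wb"); writeBin(raw, con); close(con)
  expect_error(read_smv(f), "truncated")
})

test_that("summary tables round-trip with fixed column order", {
  rows <- dataset_summary(fx_wedge_dataset()$record, laue_operators("-1"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_summary_table(rows, f)
  hdr <- strsplit(readLines(f, n = 1), ",")[[1]]
  expect_identical(hdr[1:3], c("dataset_id", "space_group_number", "a"))
  back <- read_summary_table(f)
  expect_identical(back$dataset_id, rows$dataset_id)
  expect_equal(back$isa, rows$isa, tolerance = 0.01)
  expect_equal(back$cc_half, rows$cc_half, tolerance = 0.01)
  expect_equal(back$a, rows$a, tolerance = 1e-4)
  # several rows preserve ordering
  rows3 <- rbind(rows, rows, rows)
  rows3$dataset_id <- c("z", "a", "m")
  write_summary_table(rows3, f)
  expect_identical(read_summary_table(f)$dataset_id, c("z", "a", "m"))
  # empty table -> header-only CSV
  write_summary_table(rows[0, ], f)
  expect_length(readLines(f), 1L)
})
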