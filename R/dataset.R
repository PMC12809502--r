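#' Construct an electron-diffraction dataset record
#'
#' Bundles one processed dataset: acquisition header (cell, symmetry,
#' geometry, wedge) plus the unmerged reflection table. Reflections live in a
#' plain data frame with columns `h, k, l, intensity, sigma, frame,
#' dataset_id`, one row per observation.
#'
#' @param header List with elements `unit_cell` ([unit_cell()]),
#'   `space_group_number` (1-230), `wavelength` (Angstrom),
#'   `oscillation_per_frame` (degrees, non-zero), `frame_range`
#'   (integer length-2), and optionally `detector_distance` (mm),
#'   `pixel_size` (mm), `beam_center` (pixels, length-2),
#'   `rotation_axis_azimuth` (degrees) and `extra` (named character vector of
#'   unrecognised header keys, preserved on round-trip).
#' @param reflections Data frame of observations; `sigma > 0` and
#'   `(h,k,l) != (0,0,0)` are enforced. A missing/NA `frame` column marks the
#'   dataset "frameless": frames are set to the wedge midpoint and per-frame
#'   operations are disabled.
#' @param dataset_id Identifier stamped onto all reflections.
#' @param merged Logical; `TRUE` for a merged (one row per unique index) set.
#' @return An object of class `ed_dataset`.
#' @export
ed_dataset <- function(header, reflections, dataset_id = "dataset", merged = FALSE) {
  stopifnot(is.list(header), inherits(header$unit_cell, "unit_cell"))
  if (is.null(header$wavelength) || header$wavelength <= 0)
    stop("header$wavelength must be > 0")
  if (is.null(header$oscillation_per_frame) || header$oscillation_per_frame == 0)
    stop("header$oscillation_per_frame must be non-zero")
  fr <- header$frame_range
  if (is.null(fr) || length(fr) != 2 || fr[2] < fr[1])
    stop("header$frame_range must be a non-empty [first, last]")
  if (is.null(header$space_group_number)) header$space_group_number <- 1L

  need <- c("h", "k", "l", "intensity", "sigma")
  if (!all(need %in% names(reflections)))
    stop("reflections need columns: ", paste(need, collapse = ", "))
  frameless <- FALSE
  if (is.null(reflections$frame) || all(is.na(reflections$frame))) {
    frameless <- TRUE
    reflections$frame <- rep(mean(fr), nrow(reflections))
  }
  reflections$dataset_id <- rep(dataset_id, nrow(reflections))
  if (nrow(reflections)) {
    bad <- which(!(reflections$sigma > 0))
    if (length(bad))
      stop("sigma must be > 0; first violating row: ", bad[1])
    zero <- which(reflections$h == 0 & reflections$k == 0 & reflections$l == 0)
    if (length(zero))
      stop("(0,0,0) is not a reflection; first violating row: ", zero[1])
  }
  rownames(reflections) <- NULL
  structure(list(header = header,
                 reflections = reflections[, c("h", "k", "l", "intensity",
                                               "sigma", "frame", "dataset_id")],
                 dataset_id = dataset_id,
                 merged = isTRUE(merged),
                 frameless = frameless),
            class = "ed_dataset")
}

#' @export
print.ed_dataset <- function(x, ...) {
  cat(sprintf("<ed_dataset '%s'> %d reflections, SG %d, %s\n",
              x$dataset_id, nrow(x$reflections),
              x$header$space_group_number,
              if (x$merged) "merged" else "unmerged"))
  print(x$header$unit_cell)
  invisible(x)
}

# empty reflection table with the canonical columns
empty_reflections <- function() {
  data.frame(h = integer(), k = integer(), l = integer(),
             intensity = numeric(), sigma = numeric(), frame = numeric(),
             dataset_id = character(), stringsAsFactors = FALSE)
}
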