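# On-disk artefacts: XDS_ASCII-style reflection files, XSCALE.LP correlation
# tables, SMV images and CSV summary tables.

.mandatory_items <- c("ITEM_H", "ITEM_K", "ITEM_L", "ITEM_IOBS", "ITEM_SIGMA(IOBS)")

#' Read an unmerged reflection file (XDS_ASCII dialect)
#'
#' Header lines begin with `!` and carry `KEY= value` pairs; `ITEM_*` keys
#' declare the column position of each record field, so column order is
#' arbitrary. Records are whitespace-separated numbers, terminated by
#' `!END_OF_DATA`. Unrecognised header keys are preserved for round-trip.
#'
#' @param path File to read.
#' @return An [ed_dataset()].
#' @export
read_xds_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grepl("^!", lines)
  hdr_lines <- lines[hdr_idx]
  kv <- list()
  for (ln in hdr_lines) {
    body <- sub("^!", "", ln)
    if (!grepl("=", body, fixed = TRUE)) next
    key <- trimws(sub("=.*", "", body))
    val <- trimws(sub("^[^=]*=", "", body))
    kv[[key]] <- val
  }
  miss <- setdiff(.mandatory_items, names(kv))
  if (length(miss))
    stop("format error: missing header declarations: ", paste(miss, collapse = ", "))

  item_pos <- function(key) as.integer(kv[[key]])
  cols <- c(h = item_pos("ITEM_H"), k = item_pos("ITEM_K"), l = item_pos("ITEM_L"),
            intensity = item_pos("ITEM_IOBS"), sigma = item_pos("ITEM_SIGMA(IOBS)"))
  frame_col <- if (!is.null(kv[["ITEM_ZD"]])) item_pos("ITEM_ZD") else NA_integer_

  end_hdr <- which(lines == "!END_OF_HEADER")
  start <- if (length(end_hdr)) end_hdr[1] + 1 else which(!hdr_idx)[1]
  end_data <- which(lines == "!END_OF_DATA")
  stop_at <- if (length(end_data)) end_data[1] - 1 else length(lines)
  rec_lines <- if (!is.na(start) && start <= stop_at) lines[start:stop_at] else character()
  rec_lines_idx <- if (length(rec_lines)) (start:stop_at) else integer()
  keep <- nzchar(trimws(rec_lines)) & !grepl("^!", rec_lines)
  rec_lines <- rec_lines[keep]
  rec_lines_idx <- rec_lines_idx[keep]

  parse_cell <- function(v) {
    p <- as.numeric(strsplit(trimws(v), "\\s+")[[1]])
    unit_cell(p[1], p[2], p[3], p[4], p[5], p[6])
  }
  num <- function(key, default = NULL) {
    if (is.null(kv[[key]])) return(default)
    as.numeric(strsplit(trimws(kv[[key]]), "\\s+")[[1]])
  }

  known <- c(.mandatory_items, "ITEM_ZD", "FORMAT", "MERGE",
             "SPACE_GROUP_NUMBER", "UNIT_CELL_CONSTANTS", "X-RAY_WAVELENGTH",
             "OSCILLATION_RANGE", "DATA_RANGE", "DETECTOR_DISTANCE",
             "PIXEL_SIZE", "BEAM_CENTER", "ROTATION_AXIS_AZIMUTH",
             "DATASET_ID", "NUMBER_OF_ITEMS_IN_EACH_DATA_RECORD")
  extra <- kv[setdiff(names(kv), known)]

  header <- list(
    unit_cell = if (!is.null(kv[["UNIT_CELL_CONSTANTS"]]))
      parse_cell(kv[["UNIT_CELL_CONSTANTS"]]) else unit_cell(10, 10, 10),
    space_group_number = as.integer(num("SPACE_GROUP_NUMBER", 1)),
    wavelength = num("X-RAY_WAVELENGTH", 0.0251),
    oscillation_per_frame = num("OSCILLATION_RANGE", 1),
    frame_range = as.integer(num("DATA_RANGE", c(1, 1))),
    detector_distance = num("DETECTOR_DISTANCE", NA_real_),
    pixel_size = num("PIXEL_SIZE", NA_real_),
    beam_center = num("BEAM_CENTER", c(NA_real_, NA_real_)),
    rotation_axis_azimuth = num("ROTATION_AXIS_AZIMUTH", NA_real_),
    extra = extra
  )
  merged <- identical(toupper(kv[["MERGE"]] %||% "FALSE"), "TRUE")
  dataset_id <- kv[["DATASET_ID"]] %||% sub("\\.[^.]*$", "", basename(path))

  ncol_needed <- max(cols, frame_col, na.rm = TRUE)
  if (length(rec_lines)) {
    fields <- strsplit(trimws(rec_lines), "\\s+")
    nf <- lengths(fields)
    short <- which(nf < ncol_needed)
    if (length(short))
      stop("parse error at line ", rec_lines_idx[short[1]],
           ": expected ", ncol_needed, " fields, found ", nf[short[1]])
    m <- suppressWarnings(
      matrix(as.numeric(unlist(lapply(fields, `[`, seq_len(ncol_needed)))),
             ncol = ncol_needed, byrow = TRUE))
    badrow <- which(rowSums(is.na(m)) > 0)
    if (length(badrow))
      stop("parse error at line ", rec_lines_idx[badrow[1]],
           ": non-numeric record")
    refl <- data.frame(h = as.integer(m[, cols["h"]]),
                       k = as.integer(m[, cols["k"]]),
                       l = as.integer(m[, cols["l"]]),
                       intensity = m[, cols["intensity"]],
                       sigma = m[, cols["sigma"]])
    refl$frame <- if (!is.na(frame_col)) m[, frame_col] else NA_real_
  } else {
    refl <- empty_reflections()
  }
  ed_dataset(header, refl, dataset_id = dataset_id, merged = merged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fmt_num <- function(x) sprintf("%.6g", x)

#' Write a reflection file (XDS_ASCII dialect)
#'
#' Emits a file re-readable by [read_xds_ascii()]. With `merged = TRUE` the
#' `MERGE` header key is set, the frame column is dropped, and the record
#' must contain exactly one row per Miller index.
#'
#' @param record An [ed_dataset()].
#' @param path Output file.
#' @param merged Logical merge flag.
#' @return `path`, invisibly.
#' @export
write_xds_ascii <- function(record, path, merged = record$merged) {
  hd <- record$header
  refl <- record$reflections
  if (merged) {
    key <- paste(refl$h, refl$k, refl$l)
    if (anyDuplicated(key))
      stop("merged output requires one row per unique index")
  }
  items <- c("!ITEM_H=1", "!ITEM_K=2", "!ITEM_L=3", "!ITEM_IOBS=4",
             "!ITEM_SIGMA(IOBS)=5")
  n_items <- if (merged) 5 else 6
  if (!merged) items <- c(items, "!ITEM_ZD=6")
  uc <- hd$unit_cell
  lines <- c(
    "!FORMAT=XDS_ASCII",
    sprintf("!MERGE=%s", if (merged) "TRUE" else "FALSE"),
    sprintf("!SPACE_GROUP_NUMBER= %d", hd$space_group_number),
    sprintf("!UNIT_CELL_CONSTANTS= %.4f %.4f %.4f %.4f %.4f %.4f",
            uc[["a"]], uc[["b"]], uc[["c"]],
            uc[["alpha"]], uc[["beta"]], uc[["gamma"]]),
    sprintf("!X-RAY_WAVELENGTH= %s", .fmt_num(hd$wavelength)),
    sprintf("!OSCILLATION_RANGE= %s", .fmt_num(hd$oscillation_per_frame)),
    sprintf("!DATA_RANGE= %d %d", hd$frame_range[1], hd$frame_range[2]),
    sprintf("!DATASET_ID= %s", record$dataset_id),
    sprintf("!NUMBER_OF_ITEMS_IN_EACH_DATA_RECORD=%d", n_items)
  )
  if (!is.null(hd$detector_distance) && !is.na(hd$detector_distance))
    lines <- c(lines, sprintf("!DETECTOR_DISTANCE= %s", .fmt_num(hd$detector_distance)))
  if (!is.null(hd$pixel_size) && !is.na(hd$pixel_size))
    lines <- c(lines, sprintf("!PIXEL_SIZE= %s", .fmt_num(hd$pixel_size)))
  if (!is.null(hd$beam_center) && !anyNA(hd$beam_center))
    lines <- c(lines, sprintf("!BEAM_CENTER= %s %s",
                              .fmt_num(hd$beam_center[1]), .fmt_num(hd$beam_center[2])))
  if (!is.null(hd$rotation_axis_azimuth) && !is.na(hd$rotation_axis_azimuth))
    lines <- c(lines, sprintf("!ROTATION_AXIS_AZIMUTH= %s",
                              .fmt_num(hd$rotation_axis_azimuth)))
  for (key in names(hd$extra))
    lines <- c(lines, sprintf("!%s= %s", key, hd$extra[[key]]))
  lines <- c(lines, items, "!END_OF_HEADER")
  if (nrow(refl)) {
    body <- if (merged)
      sprintf("%6d %6d %6d %15.6e %15.6e",
              refl$h, refl$k, refl$l, refl$intensity, refl$sigma)
    else
      sprintf("%6d %6d %6d %15.6e %15.6e %10.3f",
              refl$h, refl$k, refl$l, refl$intensity, refl$sigma, refl$frame)
    lines <- c(lines, body)
  }
  lines <- c(lines, "!END_OF_DATA")
  writeLines(lines, path)
  invisible(path)
}

#' Read the pairwise-correlation block of an XSCALE.LP-style file
#'
#' Looks for the inter-dataset correlation table (rows of
#' `i j n_common cc ...`) following a line containing "CORRELATIONS". Dataset
#' count is taken from `INPUT_FILE` entries when present, otherwise from the
#' largest pair index. Absent pairs stay `NA` (insufficient overlap), never 0.
#'
#' @param path File to read.
#' @return A `correlation_table`: list with `ids`, symmetric `cc` matrix
#'   (diagonal 1) and symmetric `n_common` count matrix.
#' @export
read_xscale_lp_correlations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  anchor <- grep("CORRELATIONS", lines)
  if (!length(anchor))
    stop("format error: no CORRELATIONS block found in ", path)
  inputs <- grep("INPUT_FILE", lines, value = TRUE)
  n_declared <- length(inputs)

  pair_rows <- list()
  for (ln in lines[(anchor[1] + 1):length(lines)]) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 4) next
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v[1:4])) next
    if (v[1] != round(v[1]) || v[2] != round(v[2])) next
    pair_rows[[length(pair_rows) + 1]] <- v[1:4]
  }
  n <- max(n_declared, if (length(pair_rows))
    max(vapply(pair_rows, function(r) max(r[1:2]), 0)) else 1)
  n <- as.integer(n)
  cc <- matrix(NA_real_, n, n)
  ncom <- matrix(NA_real_, n, n)
  diag(cc) <- 1
  for (r in pair_rows) {
    i <- r[1]; j <- r[2]
    if (!is.na(cc[i, j]) && i != j && abs(cc[i, j] - r[4]) > 1e-9)
      stop("conflicting duplicate CC for pair (", i, ",", j, ")")
    cc[i, j] <- cc[j, i] <- r[4]
    ncom[i, j] <- ncom[j, i] <- r[3]
  }
  structure(list(ids = as.character(seq_len(n)), cc = cc, n_common = ncom),
            class = "correlation_table")
}

#' Read an SMV (ADSC) image
#'
#' @param path File to read.
#' @return An `smv_image`: list with `header` (named character vector, keys
#'   verbatim) and `pixels` (integer matrix, `pixels[y+1, x+1]`, x = fast
#'   axis, 0-based pixel convention elsewhere in the package).
#' @export
read_smv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  probe <- readBin(con, "raw", 512)
  txt <- rawToChar(probe[probe != as.raw(0)])
  m <- regmatches(txt, regexpr("HEADER_BYTES=\\s*[0-9]+", txt))
  if (!length(m)) stop("format error: no HEADER_BYTES in SMV header")
  header_bytes <- as.integer(sub(".*=", "", m))
  if (header_bytes > 512) {
    rest <- readBin(con, "raw", header_bytes - 512)
    probe <- c(probe, rest)
  }
  txt <- rawToChar(probe[probe != as.raw(0)])
  body <- sub("^\\s*\\{", "", txt)
  body <- sub("\\}.*$", "", body)
  entries <- strsplit(body, ";")[[1]]
  entries <- trimws(entries)
  entries <- entries[nzchar(entries) & grepl("=", entries)]
  keys <- trimws(sub("=.*", "", entries))
  vals <- trimws(sub("^[^=]*=", "", entries))
  header <- stats::setNames(vals, keys)
  nx <- as.integer(header[["SIZE1"]])
  ny <- as.integer(header[["SIZE2"]])
  npix <- nx * ny
  data <- readBin(con, "integer", n = npix, size = 2, signed = FALSE,
                  endian = "little")
  if (length(data) < npix)
    stop("I/O error: truncated pixel block, expected ", 2 * npix,
         " bytes, got ", 2 * length(data))
  structure(list(header = header,
                 pixels = matrix(data, nrow = ny, ncol = nx, byrow = TRUE)),
            class = "smv_image")
}

#' Write an SMV (ADSC) image
#'
#' Header is written in the 512-byte-padded dialect with explicit
#' `BYTE_ORDER=little_endian`; pixel values above 65535 are clamped to 65535
#' with a warning reporting the count.
#'
#' @param image An `smv_image` (or list with `header`, `pixels`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_smv <- function(image, path) {
  px <- image$pixels
  ny <- nrow(px); nx <- ncol(px)
  header <- image$header
  header[["SIZE1"]] <- as.character(nx)
  header[["SIZE2"]] <- as.character(ny)
  header[["DIM"]] <- "2"
  header[["BYTE_ORDER"]] <- "little_endian"
  header[["TYPE"]] <- "unsigned_short"
  n_over <- sum(px > 65535)
  if (n_over > 0) {
    warning(n_over, " pixel(s) above 65535 clamped on SMV write")
    px[px > 65535] <- 65535
  }
  px[px < 0] <- 0
  body_keys <- setdiff(names(header), "HEADER_BYTES")
  make_txt <- function(hb) {
    paste0("{\n", sprintf("HEADER_BYTES=%5d;\n", hb),
           paste0(names(header[body_keys]), "=", header[body_keys], ";\n",
                  collapse = ""),
           "}\n")
  }
  hb <- 512
  while (nchar(make_txt(hb), type = "bytes") > hb) hb <- hb + 512
  txt <- make_txt(hb)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(txt), con)
  pad <- hb - nchar(txt, type = "bytes")
  if (pad > 0) writeBin(rep(as.raw(0x20), pad), con)
  stream <- as.integer(t(px))   # x fastest
  writeBin(stream, con, size = 2, endian = "little")
  invisible(path)
}

.summary_cols <- c("dataset_id", "space_group_number",
                   "a", "b", "c", "alpha", "beta", "gamma",
                   "volume", "isa", "r_meas", "cc_half", "completeness",
                   "resolution_estimate")

#' Write the per-dataset summary table
#'
#' CSV with fixed column order (dataset id, space group, cell, volume, ISa,
#' Rmeas, CC1/2, completeness, resolution estimate); cell parameters at 4
#' decimals, percents and ISa at 2.
#'
#' @param rows Data frame of summary rows (see [dataset_summary()]).
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(rows, path) {
  if (nrow(rows) == 0) {
    writeLines(paste(.summary_cols, collapse = ","), path)
    return(invisible(path))
  }
  out <- rows[, .summary_cols]
  f2 <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))
  f4 <- function(x) ifelse(is.na(x), "", sprintf("%.4f", x))
  body <- data.frame(
    dataset_id = out$dataset_id,
    space_group_number = out$space_group_number,
    a = f4(out$a), b = f4(out$b), c = f4(out$c),
    alpha = f4(out$alpha), beta = f4(out$beta), gamma = f4(out$gamma),
    volume = f2(out$volume), isa = f2(out$isa),
    r_meas = f4(out$r_meas), cc_half = f2(out$cc_half),
    completeness = f2(out$completeness),
    resolution_estimate = f4(out$resolution_estimate),
    stringsAsFactors = FALSE)
  utils::write.csv(body, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a summary table written by [write_summary_table()]
#'
#' @param path CSV file.
#' @return Data frame with the canonical summary columns.
#' @export
read_summary_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(dataset_id = "character"))
  for (cl in setdiff(.summary_cols, c("dataset_id", "space_group_number")))
    df[[cl]] <- as.numeric(df[[cl]])
  df
}
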