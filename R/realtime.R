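# Real-time acquisition monitor: polls a directory for completed datasets,
# processes each exactly once in screening or merging mode, keeps live
# merged statistics and evaluates the stop condition. The loop itself is a
# thin wrapper; every transition is a pure function of (state, inputs) so
# the machine is testable without waiting on a clock.

#' Real-time run configuration
#'
#' @param watch_dir Directory to monitor for reflection files (`*.HKL`).
#' @param mode `"screening"` (per-dataset indicators only) or `"merging"`
#'   (valid datasets are re-scaled and merged each iteration; requires
#'   `cell` and `laue`).
#' @param cell Known [unit_cell()] (merging mode).
#' @param laue Known `laue_group` (merging mode).
#' @param poll_interval Seconds between polls of the watch loop.
#' @param quiescence Seconds without file growth after which a dataset
#'   counts as complete (default 10); a sidecar `<file>.done` sentinel
#'   overrides the wait.
#' @param thresholds [realtime_thresholds()] gating the valid set
#'   (defaults: CC1/2 > 90%, ISa > 5).
#' @param stop_completeness Merged completeness (percent) at which the run
#'   flags stop (default 95).
#' @param stop_resolution Resolution (Angstrom) at which the stop
#'   completeness is evaluated (merging mode; default 1.3).
#' @param d_low Low-resolution limit of the completeness window (default 20).
#' @param seed Seed for the half-set splits of live statistics.
#' @return A list of class `realtime_config`.
#' @export
realtime_config <- function(watch_dir, mode = c("screening", "merging"),
                            cell = NULL, laue = NULL,
                            poll_interval = 2, quiescence = 10,
                            thresholds = realtime_thresholds(),
                            stop_completeness = 95, stop_resolution = 1.3,
                            d_low = 20, seed = 42L) {
  mode <- match.arg(mode)
  if (mode == "merging" && (is.null(cell) || is.null(laue)))
    stop("merging mode requires known cell and Laue group")
  structure(list(watch_dir = watch_dir, mode = mode, cell = cell,
                 laue = laue, poll_interval = poll_interval,
                 quiescence = quiescence, thresholds = thresholds,
                 stop_completeness = stop_completeness,
                 stop_resolution = stop_resolution, d_low = d_low,
                 seed = as.integer(seed)),
            class = "realtime_config")
}

#' Fresh live state
#'
#' @return A list of class `live_state` holding the seen/processed/valid
#'   sets, per-dataset rows and the append-only merged-statistics history.
#' @export
live_state_new <- function() {
  structure(list(
    pending = list(),                # path -> list(sig, since)
    processed = character(),
    valid_paths = character(),
    invalid = character(),           # named reasons
    rows = NULL,
    history = data.frame(iteration = integer(), n_valid = integer(),
                         completeness = numeric(), cc_half = numeric(),
                         resolution = numeric(), stop = logical()),
    iteration = 0L,
    stop_flagged = FALSE),
    class = "live_state")
}

#' Detect newly completed datasets
#'
#' A reflection file is complete when its size/mtime signature has been
#' unchanged for the configured quiescence time, or when a `<file>.done`
#' sentinel exists. Each file is reported exactly once across repeated
#' polls.
#'
#' @param state A `live_state`.
#' @param config A [realtime_config()].
#' @param now Clock time of the poll (epoch seconds; injectable for tests).
#' @return List with updated `state` and `new` (paths, in modification-time
#'   order).
#' @export
detect_complete_datasets <- function(state, config,
                                     now = as.numeric(Sys.time())) {
  files <- tryCatch(
    list.files(config$watch_dir, pattern = "\\.(HKL|hkl)$", full.names = TRUE),
    error = function(e) character())
  info <- file.info(files)
  ord <- order(info$mtime, files)
  files <- files[ord]; info <- info[ord, , drop = FALSE]
  new <- character()
  for (i in seq_along(files)) {
    f <- files[i]
    if (f %in% state$processed || f %in% names(state$invalid)) next
    if (f %in% new) next
    sig <- paste(info$size[i], as.numeric(info$mtime[i]))
    sentinel <- file.exists(paste0(f, ".done"))
    prev <- state$pending[[f]]
    if (sentinel) {
      new <- c(new, f)
    } else if (is.null(prev) || !identical(prev$sig, sig)) {
      state$pending[[f]] <- list(sig = sig, since = now)
    } else if (now - prev$since >= config$quiescence) {
      new <- c(new, f)
    }
  }
  for (f in new) state$pending[[f]] <- NULL
  list(state = state, new = new)
}

.rt_summary_row <- function(path, config) {
  tryCatch({
    rec <- read_xds_ascii(path)
    if (!is.null(config$cell)) rec$header$unit_cell <- config$cell
    laue <- config$laue
    dataset_summary(rec, laue = laue, seed = config$seed)
  }, error = function(e) {
    row <- data.frame(dataset_id = sub("\\.[^.]*$", "", basename(path)),
                      space_group_number = NA_integer_,
                      a = NA_real_, b = NA_real_, c = NA_real_,
                      alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
                      volume = NA_real_, isa = NA_real_, r_meas = NA_real_,
                      cc_half = NA_real_, completeness = NA_real_,
                      resolution_estimate = NA_real_,
                      stringsAsFactors = FALSE)
    attr(row, "error") <- conditionMessage(e)
    row
  })
}

#' Process one dataset in screening mode
#'
#' Appends the dataset's summary indicators to the live state; no merging is
#' attempted. A failing dataset yields a row of missing fields and the batch
#' continues.
#'
#' @param path Reflection file of the completed dataset.
#' @param state A `live_state`.
#' @param config A [realtime_config()].
#' @return Updated `live_state`.
#' @export
process_screening <- function(path, state, config) {
  row <- .rt_summary_row(path, config)
  state$rows <- rbind(state$rows, row)
  state$processed <- c(state$processed, path)
  state
}

#' Process one dataset in merging mode
#'
#' The dataset is evaluated in the known cell and Laue group; if it passes
#' the real-time thresholds it joins the valid set and scaling + merging is
#' re-run from scratch over all valid datasets, appending merged
#' completeness, CC1/2 and resolution to the history and evaluating the
#' stop condition (completeness at the preset resolution). A failing dataset
#' is recorded invalid with its reason and the history is unchanged.
#'
#' @inheritParams process_screening
#' @return Updated `live_state`.
#' @export
process_merging <- function(path, state, config) {
  row <- .rt_summary_row(path, config)
  state$rows <- rbind(state$rows, row)
  state$processed <- c(state$processed, path)
  if (!is.na(attr(row, "error") %||% NA)) {
    state$invalid[path] <- attr(row, "error")
    return(state)
  }
  flt <- filter_datasets(row, config$thresholds)
  if (!length(flt$picked)) {
    state$invalid[path] <- unname(flt$reasons[1])
    return(state)
  }
  state$valid_paths <- c(state$valid_paths, path)
  state <- .rt_remerge(state, config)
  state
}

.rt_remerge <- function(state, config) {
  recs <- lapply(state$valid_paths, function(p) {
    r <- read_xds_ascii(p)
    r$header$unit_cell <- config$cell
    r
  })
  laue <- config$laue
  if (length(recs) >= 2) {
    sol <- tryCatch(fit_scales(recs, laue), error = function(e) NULL)
    mg <- merge_datasets(recs, sol, laue, seed = config$seed)
  } else {
    mg <- merge_datasets(recs, NULL, laue, seed = config$seed)
  }
  all_obs <- do.call(rbind, lapply(recs, function(r) r$reflections))
  gr <- group_equivalents(all_obs, laue)
  comp <- tryCatch(
    completeness(gr, config$cell, d_max = config$d_low,
                 d_min = config$stop_resolution),
    error = function(e) NA_real_)
  cc <- cc_half(gr, seed = config$seed)
  reso <- tryCatch(suppressWarnings(estimate_resolution(mg$shells)),
                   error = function(e) NA_real_)
  state$iteration <- state$iteration + 1L
  stop_now <- !is.na(comp) && comp >= config$stop_completeness
  state$history <- rbind(state$history, data.frame(
    iteration = state$iteration, n_valid = length(state$valid_paths),
    completeness = comp, cc_half = cc$cc, resolution = reso,
    stop = stop_now))
  state$stop_flagged <- state$stop_flagged || stop_now
  state
}

#' One poll of the real-time state machine
#'
#' Detects newly completed datasets and processes each according to the
#' configured mode. Pure state transition; the [rt_watch()] loop calls it on
#' a timer.
#'
#' @param state A `live_state`.
#' @param config A [realtime_config()].
#' @param now Poll time (epoch seconds).
#' @return Updated `live_state`.
#' @export
rt_poll <- function(state, config, now = as.numeric(Sys.time())) {
  det <- detect_complete_datasets(state, config, now)
  state <- det$state
  for (f in det$new) {
    state <- if (config$mode == "screening")
      process_screening(f, state, config)
    else
      process_merging(f, state, config)
  }
  state
}

#' Watch an acquisition directory
#'
#' Polls until `max_polls` polls have happened or the stop condition is
#' flagged, persisting the state to a JSON sidecar after every poll so an
#' interrupted run can resume.
#'
#' @param config A [realtime_config()].
#' @param state Optional `live_state` to resume from (default: loaded from
#'   `state_path` when present, else fresh).
#' @param state_path JSON sidecar (default `<watch_dir>/.edbatch_state.json`).
#' @param max_polls Poll-count cap (default `Inf`; tests and batch replays
#'   use a finite cap).
#' @param sleep Sleep between polls in seconds (default
#'   `config$poll_interval`; 0 for replays).
#' @return Final `live_state`, invisibly.
#' @export
rt_watch <- function(config, state = NULL,
                     state_path = file.path(config$watch_dir,
                                            ".edbatch_state.json"),
                     max_polls = Inf, sleep = config$poll_interval) {
  if (is.null(state)) {
    state <- if (file.exists(state_path)) rt_load_state(state_path)
    else live_state_new()
  }
  polls <- 0
  while (polls < max_polls && !state$stop_flagged) {
    state <- rt_poll(state, config)
    rt_save_state(state, state_path)
    polls <- polls + 1
    if (polls < max_polls && !state$stop_flagged && sleep > 0)
      Sys.sleep(sleep)
  }
  invisible(state)
}

#' Persist / reload the live state
#'
#' @param state A `live_state`.
#' @param path JSON file.
#' @return `rt_save_state`: `path` invisibly; `rt_load_state`: the restored
#'   `live_state`.
#' @export
rt_save_state <- function(state, path) {
  payload <- list(
    pending = state$pending,
    processed = state$processed,
    valid_paths = state$valid_paths,
    invalid = as.list(state$invalid),
    rows = state$rows,
    history = state$history,
    iteration = state$iteration,
    stop_flagged = state$stop_flagged)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname rt_save_state
#' @export
rt_load_state <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- live_state_new()
  st$pending <- lapply(p$pending, function(x)
    list(sig = x$sig, since = as.numeric(x$since)))
  st$processed <- as.character(p$processed %||% character())
  st$valid_paths <- as.character(p$valid_paths %||% character())
  inv <- unlist(p$invalid)
  st$invalid <- if (is.null(inv)) character() else inv
  if (!is.null(p$rows) && length(p$rows)) st$rows <- as.data.frame(p$rows)
  if (!is.null(p$history) && length(p$history) && NROW(p$history))
    st$history <- as.data.frame(p$history)
  st$iteration <- as.integer(p$iteration %||% 0L)
  st$stop_flagged <- isTRUE(p$stop_flagged)
  st
}
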