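#' Write / read a recording in the native CSV dialect
#'
#' The contract-of-record on-disk format is a wide, human-inspectable CSV:
#' one row per sample with columns `time_s`, `ch01_wl780`..`ch15_wl780`,
#' `ch01_wl850`..`ch15_wl850`, plus a sidecar events TSV
#' (`onset`, `duration`, `condition`) next to it. Round trips are lossless to
#' full double precision.
#'
#' @param rec An `"upb_recording"` (see [simulate_recording()]).
#' @param path Path of the signal CSV. The events sidecar is written to the
#'   same path with `_events.tsv` substituted for the extension unless
#'   `events_path` is given.
#' @param events_path Optional explicit sidecar path.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an `"upb_recording"`.
#' @export
write_recording <- function(rec, path, events_path = events_sidecar(path)) {
  stopifnot(inherits(rec, "upb_recording"))
  readr::write_csv(rec$od, path)
  readr::write_tsv(rec$events, events_path)
  invisible(path)
}

events_sidecar <- function(path) {
  sub("\\.[^.]+$", "", path) |> paste0("_events.tsv")
}

#' @rdname write_recording
#' @param layout Montage tibble attached to the read recording.
#' @export
read_recording <- function(path, events_path = events_sidecar(path),
                           layout = default_montage()) {
  od <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_montage(layout)
  required <- c("time_s",
                paste0(layout$channel, "_wl780"),
                paste0(layout$channel, "_wl850"))
  missing <- setdiff(required, names(od))
  if (length(missing) > 0L) {
    stop("Recording file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dt <- diff(od$time_s)
  if (length(dt) > 0L && (max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
    stop("Recording file ", path, " has a non-uniform time axis.",
         call. = FALSE)
  }
  fs <- if (length(dt) > 0L) 1 / stats::median(dt) else NA_real_
  events <- if (file.exists(events_path)) {
    read_events(events_path)
  } else {
    tibble::tibble(onset = numeric(), duration = numeric(),
                   condition = character())
  }
  if (nrow(events) > 0L && any(events$onset > max(od$time_s))) {
    stop("Event onset beyond the end of the recording in ", events_path,
         call. = FALSE)
  }
  structure(
    list(od = od[required], events = events, layout = layout,
         sampling_rate = fs, filtered = FALSE),
    class = "upb_recording"
  )
}

#' Read an events table
#'
#' Events are a TSV with columns `onset` (s), `duration` (s) and `condition`
#' (one of `Task1`, `Task2`). Rows are returned sorted by onset. Overlapping
#' task intervals raise a warning (not an error); onsets beyond the end of a
#' recording are rejected later, at epoching time.
#'
#' @param path TSV file path.
#' @return Tibble with columns `onset`, `duration`, `condition`.
#' @export
read_events <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(ev) == 0L) {
    return(tibble::tibble(onset = numeric(), duration = numeric(),
                          condition = character()))
  }
  missing <- setdiff(c("onset", "duration", "condition"), names(ev))
  if (length(missing) > 0L) {
    stop("Events file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(ev$condition), c("Task1", "Task2"))
  if (length(bad) > 0L) {
    stop("Events file ", path, " has unknown condition label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ev <- dplyr::arrange(ev[c("onset", "duration", "condition")], .data$onset)
  if (nrow(ev) > 1L &&
      any(ev$onset[-1L] < (ev$onset + ev$duration)[-nrow(ev)])) {
    warning("Overlapping task intervals in ", path, call. = FALSE)
  }
  ev
}

#' @export
print.upb_recording <- function(x, ...) {
  cat("<upb_recording> ", nrow(x$od), " samples x ", nrow(x$layout),
      " channels x 2 wavelengths @ ", round(x$sampling_rate, 3), " Hz\n",
      sep = "")
  cat("  events: ", nrow(x$events), " (",
      paste(unique(x$events$condition), collapse = ", "), ")",
      if (isTRUE(x$filtered)) "  [band-passed]", "\n", sep = "")
  invisible(x)
}
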