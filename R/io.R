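# Readers and writers. Two plain-text dialects only: comma-separated values
# with a header row, and JSON sidecars/reports. (No HDF5: no R binding is
# available in the supported environment; no proprietary acquisition
# formats — video handling and ROI extraction are upstream of this package.)

#' Read calcium traces from delimited text
#'
#' Expects a neuron x frame layout: one row per neuron, one column per
#' frame, comma-separated with a header row (as written by
#' [write_traces()]). Delimited text carries no sampling rate, so it must
#' be supplied.
#'
#' @param path CSV file path.
#' @param sampling_rate frame rate in Hz (required).
#' @return A [calcium_traces()].
#' @export
read_traces <- function(path, sampling_rate = NULL) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  if (is.null(sampling_rate)) {
    stop_invalid("sampling_rate is required when reading delimited traces")
  }
  df <- tryCatch(utils::read.csv(path, header = TRUE, check.names = FALSE),
                 error = function(e) stop_invalid("malformed trace file %s: %s",
                                                  path, conditionMessage(e)))
  m <- as.matrix(df)
  if (!is.numeric(m)) stop_invalid("trace file %s contains non-numeric data", path)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_invalid("non-finite trace value at neuron %d, frame %d in %s",
                 bad[1, 1], bad[1, 2], path)
  }
  dimnames(m) <- NULL
  calcium_traces(m, sampling_rate)
}

#' Write calcium traces to delimited text
#' @param traces a [calcium_traces()].
#' @param path output CSV path.
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "calcium_traces"))
  m <- traces$values
  colnames(m) <- paste0("frame_", seq_len(ncol(m)))
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' Read behavioral tracking from delimited text
#'
#' Expects columns `time` plus one (`x`) or two (`x`, `y`) position
#' coordinates in cm; timestamps must be strictly increasing.
#'
#' @param path CSV file path.
#' @param arena_bounds optional per-coordinate upper bounds (cm); defaults
#'   to the observed position maxima.
#' @return A [behavior_track()].
#' @export
read_behavior <- function(path, arena_bounds = NULL) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  df <- utils::read.csv(path, header = TRUE)
  if (ncol(df) < 2L || ncol(df) > 3L) {
    stop_invalid("behavior file needs columns time + 1 or 2 coordinates")
  }
  tm <- df[[1L]]
  if (any(diff(tm) <= 0)) {
    stop_invalid("behavior timestamps must be strictly increasing (duplicate or backwards time in %s)", path)
  }
  pos <- as.matrix(df[, -1L, drop = FALSE])
  if (is.null(arena_bounds)) arena_bounds <- apply(pos, 2L, max)
  behavior_track(tm, pos, arena_bounds)
}

#' Write behavioral tracking to delimited text
#' @param track a [behavior_track()].
#' @param path output CSV path.
#' @export
write_behavior <- function(track, path) {
  stopifnot(inherits(track, "behavior_track"))
  df <- data.frame(time = track$timestamps)
  df$x <- track$position[, 1]
  if (track$ndim == 2L) df$y <- track$position[, 2]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Align behavior onto the imaging frame clock
#'
#' Linearly interpolates the tracked position onto the imaging frame
#' timestamps (the miniscope and the behavior camera run on different
#' clocks; the acquisition records timestamps for both). Frames outside
#' the behavior coverage get `NA` positions, which downstream
#' discretization turns into excluded frames. Coverage below 99% of the
#' frame range is an alignment error.
#'
#' @param track a [behavior_track()] on the behavior-camera clock.
#' @param frame_timestamps imaging frame times (seconds).
#' @return A [behavior_track()] on the frame clock (positions `NA` outside
#'   coverage).
#' @export
align_behavior_to_frames <- function(track, frame_timestamps) {
  stopifnot(inherits(track, "behavior_track"))
  rng <- range(track$timestamps)
  covered <- frame_timestamps >= rng[1] & frame_timestamps <= rng[2]
  coverage <- mean(covered)
  if (coverage < 0.99) {
    stop_invalid("behavior covers only %.1f%% of the imaging frames (range %.2f-%.2f s vs frames %.2f-%.2f s)",
                 100 * coverage, rng[1], rng[2],
                 min(frame_timestamps), max(frame_timestamps))
  }
  pos <- vapply(seq_len(track$ndim), function(d) {
    out <- stats::approx(track$timestamps, track$position[, d],
                         xout = frame_timestamps, rule = 1)$y
    out
  }, numeric(length(frame_timestamps)))
  pos <- matrix(pos, ncol = track$ndim)
  behavior_track(frame_timestamps, pos, track$arena_bounds)
}
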