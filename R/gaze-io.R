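#' Gaze sample trace
#'
#' A uniformly sampled stream of 2D gaze positions with per-sample validity
#' flags, the raw input to the whole pipeline. Invalid samples (tracker
#' loss, blinks) are retained in place so the time base stays regular; their
#' coordinates may be `NA`.
#'
#' @param time sample times in seconds, strictly increasing.
#' @param x,y gaze position in screen pixels.
#' @param valid logical vector, `TRUE` where the tracker reported a usable
#'   sample. Coordinates must be finite wherever `valid` is `TRUE`.
#' @param subject_id identifier carried through to result tables.
#' @param rate_hz nominal sampling rate; the median inter-sample interval
#'   must be within 20% of `1/rate_hz`.
#'
#' @return An object of class `gaze_trace`.
#' @export
gaze_trace <- function(time, x, y, valid = rep(TRUE, length(time)),
                       subject_id = NA_character_, rate_hz = 120) {
  n <- length(time)
  if (n == 0L) stop("empty gaze trace", call. = FALSE)
  stopifnot(length(x) == n, length(y) == n, length(valid) == n)
  time <- as.numeric(time); x <- as.numeric(x); y <- as.numeric(y)
  valid <- as.logical(valid)
  valid[is.na(valid)] <- FALSE
  if (any(diff(time) <= 0)) {
    stop("gaze trace integrity error: sample times must be strictly increasing",
         call. = FALSE)
  }
  if (n > 1L) {
    med_dt <- stats::median(diff(time))
    if (abs(med_dt - 1 / rate_hz) > 0.2 / rate_hz) {
      stop(sprintf(
        "gaze trace integrity error: median interval %.4gs is not within 20%% of 1/%g Hz",
        med_dt, rate_hz), call. = FALSE)
    }
  }
  if (any(valid & (!is.finite(x) | !is.finite(y)))) {
    stop("gaze trace integrity error: non-finite coordinates on valid samples",
         call. = FALSE)
  }
  structure(list(subject_id = subject_id, time = time, x = x, y = y,
                 valid = valid, rate_hz = rate_hz),
            class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("<gaze_trace> subject %s: %d samples @ %g Hz, %.1f s, %.1f%% valid\n",
              x$subject_id, length(x$time), x$rate_hz,
              diff(range(x$time)), 100 * mean(x$valid)))
  invisible(x)
}

#' Read and write gaze sample files
#'
#' Gaze files are delimited text (comma or tab, auto-detected) with a header
#' row and columns `time` (seconds), `x`, `y` (pixels) and `valid` (0/1 or
#' logical). Rows flagged invalid are retained with `valid = FALSE`.
#'
#' @param path file to read or write.
#' @param subject_id subject identifier to attach (defaults to the file name).
#' @param rate_hz nominal sampling rate of the recording.
#' @return `read_gaze()` returns a validated [gaze_trace()]; `write_gaze()`
#'   returns `path` invisibly.
#' @export
read_gaze <- function(path, subject_id = NULL, rate_hz = 120) {
  dt <- data.table::fread(path, header = TRUE)
  need <- c("time", "x", "y", "valid")
  if (!all(need %in% names(dt))) {
    stop(sprintf("gaze file format error: missing column(s) %s in %s",
                 paste(setdiff(need, names(dt)), collapse = ", "), path),
         call. = FALSE)
  }
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  gaze_trace(time = dt$time, x = dt$x, y = dt$y,
             valid = as.logical(dt$valid),
             subject_id = subject_id, rate_hz = rate_hz)
}

#' @rdname read_gaze
#' @param trace a [gaze_trace()] to write.
#' @export
write_gaze <- function(trace, path) {
  stopifnot(inherits(trace, "gaze_trace"))
  # full-precision text so a write/read round trip is bit-exact
  fmt <- function(z) ifelse(is.na(z), "", sprintf("%.17g", z))
  data.table::fwrite(
    data.table::data.table(time = fmt(trace$time), x = fmt(trace$x),
                           y = fmt(trace$y),
                           valid = as.integer(trace$valid)),
    path, quote = FALSE)
  invisible(path)
}

# labels an event log may contain
.event_labels <- c("rest_on", "rest_off", "mat_problem_on", "mat_click",
                   "vft_on", "vft_off")

#' Task event log
#'
#' Ordered markers delimiting the analysis periods: rest onset/offset,
#' mental-arithmetic problem onsets and the mouse clicks ending each
#' calculation, and verbal-fluency onset/offset.
#'
#' @param time event times in seconds, non-decreasing.
#' @param label one of `rest_on`, `rest_off`, `mat_problem_on`, `mat_click`,
#'   `vft_on`, `vft_off`.
#' @return A `data.frame` of class `event_log` with columns `time`, `label`.
#' @export
event_log <- function(time, label) {
  stopifnot(length(time) == length(label))
  label <- as.character(label)
  bad <- setdiff(unique(label), .event_labels)
  if (length(bad)) {
    stop("unknown event label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(time)) {
    stop("event log integrity error: times must be non-decreasing", call. = FALSE)
  }
  structure(data.frame(time = as.numeric(time), label = label,
                       stringsAsFactors = FALSE),
            class = c("event_log", "data.frame"))
}

#' @rdname event_log
#' @param path delimited text file with columns `time`, `label`.
#' @export
read_events <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  if (!all(c("time", "label") %in% names(dt))) {
    stop("event file format error: need columns time, label", call. = FALSE)
  }
  event_log(dt$time, dt$label)
}

#' @rdname event_log
#' @param events an `event_log` to write.
#' @export
write_events <- function(events, path) {
  data.table::fwrite(as.data.frame(events), path)
  invisible(path)
}

#' Derive analysis windows from an event log
#'
#' Rest is the half-open interval `[rest_on, rest_off)`; verbal fluency is
#' `[vft_on, vft_off)`; mental arithmetic is the union of calculation
#' periods, each running from a problem's presentation to the participant's
#' first subsequent mouse click. Problems never followed by a click (time
#' outs) have no defined end and are dropped with a warning; the spoken
#' answer interval after the click is likewise excluded.
#'
#' @param events an [event_log()].
#' @return A `data.frame` of class `period_windows` with columns `period`
#'   (`REST`, `MAT`, `VFT`), `start`, `end` (seconds, half-open).
#' @export
windows_from_events <- function(events) {
  stopifnot(inherits(events, "event_log"))
  out <- list()
  grab <- function(lab) events$time[events$label == lab]
  r_on <- grab("rest_on"); r_off <- grab("rest_off")
  if (length(r_on) && length(r_off)) {
    out[[length(out) + 1L]] <- data.frame(period = "REST", start = r_on[1L],
                                          end = r_off[1L])
  }
  v_on <- grab("vft_on"); v_off <- grab("vft_off")
  if (length(v_on) && length(v_off)) {
    out[[length(out) + 1L]] <- data.frame(period = "VFT", start = v_on[1L],
                                          end = v_off[1L])
  }
  p_on <- grab("mat_problem_on"); clicks <- grab("mat_click")
  if (length(p_on)) {
    ends <- vapply(seq_along(p_on), function(i) {
      limit <- if (i < length(p_on)) p_on[i + 1L] else Inf
      cand <- clicks[clicks > p_on[i] & clicks <= limit]
      if (length(cand)) cand[1L] else NA_real_
    }, numeric(1))
    if (anyNA(ends)) {
      warning(sprintf("%d arithmetic problem(s) without a terminating click dropped",
                      sum(is.na(ends))), call. = FALSE)
    }
    keep <- !is.na(ends)
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(period = "MAT", start = p_on[keep],
                                            end = ends[keep])
    }
  }
  win <- do.call(rbind, out)
  if (is.null(win) || any(win$end <= win$start)) {
    stop("degenerate analysis windows derived from event log", call. = FALSE)
  }
  win <- win[order(win$start), , drop = FALSE]
  rownames(win) <- NULL
  structure(win, class = c("period_windows", "data.frame"))
}

#' Screen a trace for data quality
#'
#' Recordings with too little valid data are excluded from analysis. The
#' threshold is a study-level choice (the default 0.70 is a configurable
#' placeholder, not an established criterion).
#'
#' @param trace a [gaze_trace()].
#' @param min_valid_fraction minimum tolerated fraction of valid samples.
#' @return list with `pass` (logical) and `valid_fraction`.
#' @export
quality_screen <- function(trace, min_valid_fraction = 0.70) {
  stopifnot(inherits(trace, "gaze_trace"))
  vf <- mean(trace$valid)
  list(pass = vf >= min_valid_fraction, valid_fraction = vf)
}
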