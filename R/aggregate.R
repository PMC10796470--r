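#' Aggregate saccades into per-period parameters
#'
#' Produces the three parameters of interest — frequency (events/s), mean
#' amplitude (deg) and mean velocity (deg/s) — per period and component for
#' one subject. A saccade belongs to a period iff its onset time lies in
#' one of the period's half-open intervals, which assigns
#' boundary-straddling events unambiguously. The frequency denominator is
#' the analysed duration: total window time minus time covered by invalid
#' samples (so tracker dropout does not deflate frequency); set
#' `use_valid_time = FALSE` for the raw-duration convention.
#'
#' Cells with no events have `frequency = 0` but undefined (`NA`) mean
#' amplitude and mean velocity — never 0.
#'
#' @param saccades data.frame from [detect_saccades()].
#' @param windows a `period_windows` data.frame from [windows_from_events()].
#' @param trace the [gaze_trace()] the saccades came from (supplies the
#'   validity mask and sampling rate for the valid-time denominator).
#' @param subject_id,group identifiers copied into the output rows.
#' @param use_valid_time subtract invalid-sample time from the denominator?
#' @return A `data.frame`, one row per period x component: `subject_id`,
#'   `group`, `period`, `component`, `frequency`, `mean_amplitude`,
#'   `mean_velocity`, `n_events`, `analyzed_duration`.
#' @export
aggregate_params <- function(saccades, windows, trace,
                             subject_id = trace$subject_id, group = NA_character_,
                             use_valid_time = TRUE) {
  stopifnot(inherits(windows, "period_windows"), inherits(trace, "gaze_trace"))
  periods <- unique(windows$period)
  dt_nom <- 1 / trace$rate_hz
  # membership of a time point in a set of sorted non-overlapping intervals
  in_intervals <- function(t, w) {
    i <- findInterval(t, w$start)
    i >= 1L & t < w$end[pmax(i, 1L)]
  }
  rows <- list()
  for (p in periods) {
    w <- windows[windows$period == p, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    dur <- sum(w$end - w$start)
    if (use_valid_time) {
      # each sample accounts for one nominal interval of recording time
      in_w <- in_intervals(trace$time, w)
      dur <- dur - sum(in_w & !trace$valid) * dt_nom
    }
    if (dur <= 0) stop(sprintf("zero analysed duration in period %s", p),
                       call. = FALSE)
    for (comp in c("H", "V")) {
      s <- saccades[saccades$component == comp, , drop = FALSE]
      s <- s[in_intervals(s$onset_t, w), , drop = FALSE]
      n <- nrow(s)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject_id, group = group, period = p, component = comp,
        frequency = n / dur,
        mean_amplitude = if (n) mean(s$amplitude_deg) else NA_real_,
        mean_velocity = if (n) mean(s$mean_velocity) else NA_real_,
        n_events = n, analyzed_duration = dur, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort parameter table and group summary
#'
#' Stacks per-subject parameter rows into the tidy table the statistics
#' layer consumes, and summarises it as mean and SD per group x period x
#' component cell for each of the three parameters (the layout of a
#' standard descriptive results table, 1-decimal report rounding).
#'
#' @param params data.frame of rows from [aggregate_params()] (all subjects).
#' @return list with `params` (the input, ordered) and `summary` (one row
#'   per group x period x component with `*_mean` and `*_sd` columns and
#'   `n` subjects contributing).
#' @export
cohort_table <- function(params) {
  stopifnot(all(c("subject_id", "group", "period", "component",
                  "frequency", "mean_amplitude", "mean_velocity") %in% names(params)))
  if (length(unique(params$group)) < 1L) stop("no groups present", call. = FALSE)
  key <- interaction(params$group, params$period, params$component, drop = TRUE)
  cells <- split(params, key)
  summ <- do.call(rbind, lapply(cells, function(d) {
    data.frame(group = d$group[1], period = d$period[1],
               component = d$component[1], n = nrow(d),
               frequency_mean = mean(d$frequency, na.rm = TRUE),
               frequency_sd = stats::sd(d$frequency, na.rm = TRUE),
               mean_amplitude_mean = mean(d$mean_amplitude, na.rm = TRUE),
               mean_amplitude_sd = stats::sd(d$mean_amplitude, na.rm = TRUE),
               mean_velocity_mean = mean(d$mean_velocity, na.rm = TRUE),
               mean_velocity_sd = stats::sd(d$mean_velocity, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  summ <- summ[order(summ$group, summ$period, summ$component), , drop = FALSE]
  rownames(summ) <- NULL
  # single-subject cells have no SD estimate; report 0 spread, not NA
  for (cl in grep("_sd$", names(summ), value = TRUE)) {
    summ[[cl]][is.na(summ[[cl]])] <- 0
  }
  ord <- order(params$subject_id, params$period, params$component)
  list(params = params[ord, , drop = FALSE], summary = summ)
}
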