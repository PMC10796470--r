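#' Saccade detection configuration
#'
#' Velocity-threshold (I-VT) detection: samples whose component speed meets
#' or exceeds `velocity_threshold` are saccadic. Two candidate events are
#' counted as independent saccades when they are separated by an interval
#' of `min_interval_s` or longer, or by at least `min_subthreshold_samples`
#' consecutive sub-threshold samples; otherwise they are merged into one
#' event. The two clauses coincide at exactly 120 Hz (6 samples = 50 ms)
#' and are both kept so the rule generalises to other rates. The interval
#' between two events is measured from the first sub-threshold sample after
#' the first event to the onset sample of the second, i.e. the duration
#' covered by the sub-threshold stretch.
#'
#' @param velocity_threshold deg/s; default 100.
#' @param min_interval_s seconds; default 0.050.
#' @param min_subthreshold_samples count; default 6.
#' @param mode `"per_component"` (default): detect independently on the
#'   horizontal and vertical velocity channels. `"magnitude"`: detect on the
#'   2D speed, then measure each component of every event (sensitivity
#'   analysis only).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(velocity_threshold = 100,
                             min_interval_s = 0.050,
                             min_subthreshold_samples = 6L,
                             mode = c("per_component", "magnitude")) {
  stopifnot(velocity_threshold > 0, min_interval_s > 0,
            min_subthreshold_samples >= 1)
  structure(list(velocity_threshold = velocity_threshold,
                 min_interval_s = min_interval_s,
                 min_subthreshold_samples = as.integer(min_subthreshold_samples),
                 mode = match.arg(mode)),
            class = "detection_config")
}

# Runs of TRUE in a logical vector -> matrix of (start, end) indices, inclusive.
.runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# Core single-channel detector. speed: unsigned velocity samples; pos:
# positions at the same sample indices (pos has one more usable entry than
# speed: velocity sample i spans positions i..i+1); valid: velocity validity.
.detect_channel <- function(time, speed, pos, valid, component, config) {
  supra <- !is.na(speed) & valid & speed >= config$velocity_threshold
  if (!any(supra)) return(.empty_saccades())
  runs <- .runs(supra)
  nr <- nrow(runs)
  if (nr > 1L) {
    # gap between run j and j+1: sub-threshold samples (and possibly
    # invalid ones); measure its duration from the first gap sample to the
    # next onset sample
    gs <- runs[-nr, "end"] + 1L        # first gap sample
    ge <- runs[-1L, "start"] - 1L      # last gap sample
    n_sub <- ge - gs + 1L
    gap_t <- time[runs[-1L, "start"]] - time[gs]
    civ <- cumsum(!valid)
    gap_has_invalid <- (civ[ge] - civ[gs - 1L]) > 0L
    gap_has_invalid[gs == 1L] <- civ[ge[gs == 1L]] > 0L
    merge <- (gap_t < config$min_interval_s) &
      (n_sub < config$min_subthreshold_samples) &
      !gap_has_invalid
    grp <- cumsum(c(TRUE, !merge))
  } else {
    grp <- 1L
  }
  onset <- runs[match(unique(grp), grp), "start"]
  offset_last <- tapply(runs[, "end"], grp, max)  # last supra sample
  .measure_events(time, speed, pos, as.integer(onset),
                  as.integer(offset_last), component)
}

# Measure events given onset / last-supra sample indices (velocity index
# space). Event samples run onset..offset_last inclusive (merged-gap samples
# belong to the event); amplitude is the component displacement between the
# position at onset and the position one past the last event sample.
# Within an event all speeds are finite (runs never bridge invalid
# samples), so segment means come from a cumulative sum.
.measure_events <- function(time, speed, pos, onset, offset_last, component) {
  disp <- pos[offset_last + 1L] - pos[onset]
  sgn <- ifelse(is.na(disp) | disp == 0, 1L, as.integer(sign(disp)))
  cs <- cumsum(c(0, ifelse(is.na(speed), 0, speed)))
  mv <- (cs[offset_last + 1L] - cs[onset]) / (offset_last - onset + 1L)
  data.frame(component = component,
             onset_idx = onset, offset_idx = offset_last + 1L,
             onset_t = time[onset], offset_t = time[offset_last + 1L],
             amplitude_deg = abs(disp), mean_velocity = mv,
             direction_sign = sgn, stringsAsFactors = FALSE)
}

.empty_saccades <- function() {
  data.frame(component = character(), onset_idx = integer(),
             offset_idx = integer(), onset_t = numeric(), offset_t = numeric(),
             amplitude_deg = numeric(), mean_velocity = numeric(),
             direction_sign = integer(), stringsAsFactors = FALSE)
}

#' Detect saccades on one velocity component
#'
#' Maximal runs of samples at or above the velocity threshold become
#' candidate events; neighbouring candidates are merged when the gap
#' between them is shorter than both the time and the sample-count
#' independence limits. Invalid samples terminate candidate runs and are
#' never bridged: dropouts split events. Each event is measured as its
#' unsigned component displacement from onset to offset (amplitude, deg)
#' and the arithmetic mean of component speeds over its samples (mean
#' velocity, deg/s).
#'
#' @param vel a `velocity_trace` from [component_velocity()].
#' @param component `"H"` or `"V"`.
#' @param config a [detection_config()].
#' @param positions optional [angular_trace()] supplying the positions used
#'   for amplitude measurement; required for amplitudes (the pipeline passes
#'   the smoothed angular trace).
#' @return A `data.frame`, one row per saccade: `component`, `onset_idx`,
#'   `offset_idx` (half-open, velocity-sample indices), `onset_t`,
#'   `offset_t`, `amplitude_deg`, `mean_velocity`, `direction_sign`.
#' @export
detect_component <- function(vel, component = c("H", "V"), config = detection_config(),
                             positions = NULL) {
  stopifnot(inherits(vel, "velocity_trace"))
  component <- match.arg(component)
  speed <- if (component == "H") vel$speed_x else vel$speed_y
  if (is.null(positions)) {
    # integrate velocity when no position trace is supplied
    dt <- diff(vel$time)
    sv <- if (component == "H") vel$vx else vel$vy
    sv0 <- ifelse(is.na(sv), 0, sv)
    pos <- c(0, cumsum(sv0[-length(sv0)] * dt))
    pos <- c(pos, pos[length(pos)] + sv0[length(sv0)] * dt[length(dt)])[seq_along(vel$time)]
  } else {
    stopifnot(inherits(positions, "angular_trace"))
    pos <- if (component == "H") positions$x_deg else positions$y_deg
  }
  .detect_channel(vel$time, speed, pos, vel$valid, component, config)
}

#' Detect saccades on both components
#'
#' Runs [detect_component()] on the horizontal and vertical channels (the
#' default), or — in `"magnitude"` mode — detects on the 2D velocity
#' magnitude and measures each component of every detected event.
#'
#' @inheritParams detect_component
#' @param angular the smoothed [angular_trace()] the velocities came from.
#' @return A `data.frame` of saccades for both components.
#' @export
detect_saccades <- function(vel, angular, config = detection_config()) {
  if (config$mode == "per_component") {
    out <- rbind(detect_component(vel, "H", config, angular),
                 detect_component(vel, "V", config, angular))
  } else {
    speed2d <- sqrt(vel$vx^2 + vel$vy^2)
    ev <- .detect_channel(vel$time, speed2d, rep(0, length(vel$time)),
                          vel$valid, "2D", config)
    out <- .empty_saccades()
    for (comp in c("H", "V")) {
      if (nrow(ev)) {
        speed <- if (comp == "H") vel$speed_x else vel$speed_y
        pos <- if (comp == "H") angular$x_deg else angular$y_deg
        m <- .measure_events(vel$time, speed, pos, ev$onset_idx,
                             ev$offset_idx - 1L, comp)
        out <- rbind(out, m)
      }
    }
  }
  rownames(out) <- NULL
  out
}
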