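#' Three-point moving-average smoothing
#'
#' Replaces each interior sample by the mean of itself and its two
#' neighbours, per axis; the first and last samples keep their raw values.
#' A window containing an invalid sample yields an invalid (NA) output
#' sample, so tracker loss propagates by one sample on each side rather
#' than leaking interpolated values into detection.
#'
#' @param trace an [angular_trace()].
#' @return A smoothed `angular_trace` of the same length.
#' @export
smooth_ma3 <- function(trace) {
  stopifnot(inherits(trace, "angular_trace"))
  n <- length(trace$time)
  if (sum(trace$valid) < 3L) stop("smooth_ma3 needs at least 3 valid samples",
                                  call. = FALSE)
  ma3 <- function(z) {
    s <- z
    if (n >= 3L) s[2:(n - 1L)] <- (z[1:(n - 2L)] + z[2:(n - 1L)] + z[3:n]) / 3
    s
  }
  v <- trace$valid
  vout <- v
  if (n >= 3L) vout[2:(n - 1L)] <- v[1:(n - 2L)] & v[2:(n - 1L)] & v[3:n]
  x <- ma3(trace$x_deg); y <- ma3(trace$y_deg)
  x[!vout] <- NA_real_; y[!vout] <- NA_real_
  angular_trace(trace$time, x, y, vout, subject_id = trace$subject_id)
}

#' Per-component gaze velocity
#'
#' Signed forward difference per axis: `v[i] = (x[i+1] - x[i]) / (t[i+1] -
#' t[i])`, assigned to sample `i`; the last sample has no velocity. A
#' velocity sample spanning an invalid position on either side is invalid.
#' A central-difference variant is available; the forward scheme is the
#' default because the independence rule of the detector counts raw
#' samples, and the forward difference keeps a one-to-one correspondence
#' between velocity samples and inter-sample intervals.
#'
#' @param trace an [angular_trace()] (normally smoothed first).
#' @param scheme `"forward"` (default) or `"central"`.
#' @return A `velocity_trace`: list with `time`, `vx`, `vy` (signed, deg/s),
#'   `speed_x`, `speed_y` (unsigned), `valid`.
#' @export
component_velocity <- function(trace, scheme = c("forward", "central")) {
  stopifnot(inherits(trace, "angular_trace"))
  scheme <- match.arg(scheme)
  n <- length(trace$time)
  if (n < 2L) stop("component_velocity needs at least 2 samples", call. = FALSE)
  t <- trace$time; x <- trace$x_deg; y <- trace$y_deg; v <- trace$valid
  vx <- vy <- rep(NA_real_, n)
  vv <- rep(FALSE, n)
  if (scheme == "forward") {
    i <- seq_len(n - 1L)
    dt <- t[i + 1L] - t[i]
    vx[i] <- (x[i + 1L] - x[i]) / dt
    vy[i] <- (y[i + 1L] - y[i]) / dt
    vv[i] <- v[i] & v[i + 1L]
  } else {
    i <- 2:(n - 1L)
    dt <- t[i + 1L] - t[i - 1L]
    vx[i] <- (x[i + 1L] - x[i - 1L]) / dt
    vy[i] <- (y[i + 1L] - y[i - 1L]) / dt
    vv[i] <- v[i - 1L] & v[i + 1L]
  }
  vx[!vv] <- NA_real_; vy[!vv] <- NA_real_
  structure(list(subject_id = trace$subject_id, time = t, vx = vx, vy = vy,
                 speed_x = abs(vx), speed_y = abs(vy), valid = vv),
            class = "velocity_trace")
}

#' Standard preprocessing chain
#'
#' Pixel trace to component velocities: visual-angle conversion, 3-point
#' moving-average smoothing, then forward differencing — smoothing precedes
#' differentiation.
#'
#' @param trace a [gaze_trace()].
#' @param geometry a [screen_geometry()].
#' @inheritParams component_velocity
#' @return list with `angular` (smoothed [angular_trace()]) and `velocity`
#'   (`velocity_trace`).
#' @export
preprocess_trace <- function(trace, geometry, scheme = "forward") {
  ang <- smooth_ma3(pixels_to_degrees(trace, geometry))
  list(angular = ang, velocity = component_velocity(ang, scheme = scheme))
}
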