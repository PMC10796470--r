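#' Screen geometry for visual-angle conversion
#'
#' Describes the projection surface on which gaze was recorded: its pixel
#' resolution, physical size, and the viewing distance of the observer.
#' Pixels need not be square (a projected 1024 x 768 image on a
#' 200 cm x 152 cm screen is not), so the horizontal and vertical axes are
#' converted independently.
#'
#' @param width_px,height_px screen resolution in pixels.
#' @param width_cm,height_cm physical screen size in centimetres.
#' @param viewing_distance_cm eye-to-screen distance in centimetres.
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry(1024, 768, 200, 152, 232)
#' @export
screen_geometry <- function(width_px = 1024, height_px = 768,
                            width_cm = 200, height_cm = 152,
                            viewing_distance_cm = 232) {
  vals <- c(width_px = width_px, height_px = height_px,
            width_cm = width_cm, height_cm = height_cm,
            viewing_distance_cm = viewing_distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen_geometry fields must be finite and > 0", call. = FALSE)
  }
  structure(as.list(vals), class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px on %.1f x %.1f cm at %.1f cm\n",
              x$width_px, x$height_px, x$width_cm, x$height_cm,
              x$viewing_distance_cm))
  cat(sprintf("  half-width %.1f deg, half-height %.1f deg\n",
              atan2(x$width_cm / 2, x$viewing_distance_cm) * 180 / pi,
              atan2(x$height_cm / 2, x$viewing_distance_cm) * 180 / pi))
  invisible(x)
}

#' Convert pixel gaze coordinates to degrees of visual angle
#'
#' Exact per-axis arctangent conversion about the screen centre. At wide
#' fields of view (the default geometry spans ~47 deg horizontally) the
#' small-angle approximation (a constant deg/px factor) is materially wrong
#' at the edges, so the full arctangent is used:
#' `x_deg = atan((x_px - width_px/2) * (width_cm/width_px) / distance_cm)`
#' and analogously for y. y grows downward in pixel space and is kept that
#' way in degrees; detection and measurement only ever use differences, so
#' the orientation convention is immaterial.
#'
#' @param trace a [gaze_trace()].
#' @param geometry a [screen_geometry()].
#'
#' @return An `angular_trace`: list with `time`, `x_deg`, `y_deg`, `valid`.
#' @export
pixels_to_degrees <- function(trace, geometry) {
  stopifnot(inherits(trace, "gaze_trace"), inherits(geometry, "screen_geometry"))
  d <- geometry$viewing_distance_cm
  x_cm <- (trace$x - geometry$width_px / 2) * (geometry$width_cm / geometry$width_px)
  y_cm <- (trace$y - geometry$height_px / 2) * (geometry$height_cm / geometry$height_px)
  angular_trace(time = trace$time,
                x_deg = atan(x_cm / d) * 180 / pi,
                y_deg = atan(y_cm / d) * 180 / pi,
                valid = trace$valid,
                subject_id = trace$subject_id)
}

#' Inverse of [pixels_to_degrees()]
#'
#' Maps visual angles back to pixel coordinates; used by the synthetic
#' trace generator, which works in degrees.
#'
#' @param x_deg,y_deg angles in degrees relative to screen centre.
#' @param geometry a [screen_geometry()].
#' @return list with `x`, `y` pixel coordinates.
#' @export
degrees_to_pixels <- function(x_deg, y_deg, geometry) {
  d <- geometry$viewing_distance_cm
  list(x = geometry$width_px / 2 +
         tan(x_deg * pi / 180) * d * (geometry$width_px / geometry$width_cm),
       y = geometry$height_px / 2 +
         tan(y_deg * pi / 180) * d * (geometry$height_px / geometry$height_cm))
}

#' @rdname pixels_to_degrees
#' @param time,x_deg,y_deg,valid,subject_id components of the angular trace.
#' @export
angular_trace <- function(time, x_deg, y_deg, valid = rep(TRUE, length(time)),
                          subject_id = NA_character_) {
  n <- length(time)
  stopifnot(length(x_deg) == n, length(y_deg) == n, length(valid) == n)
  structure(list(subject_id = subject_id, time = as.numeric(time),
                 x_deg = as.numeric(x_deg), y_deg = as.numeric(y_deg),
                 valid = as.logical(valid)),
            class = "angular_trace")
}
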