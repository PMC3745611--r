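#' Screen geometry for pixel/degree conversion
#'
#' Describes the stimulus display as seen by the participant: viewing
#' distance, pixel pitch and resolution. All gaze quantities in gazekit are
#' expressed in degrees of visual angle with the origin at the screen
#' center, +x rightward and +y upward; pixels appear only at the I/O edges
#' and are converted through this geometry.
#'
#' @param viewing_distance_cm Distance from the eye to the screen, cm.
#' @param pixels_per_cm Pixel density of the display, px/cm.
#' @param resolution Integer vector `c(width, height)` in pixels.
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry(57, 28.4, c(1024, 768))
#' pixels_to_degrees(data.frame(x = 512, y = 384), geom)
#' @export
screen_geometry <- function(viewing_distance_cm = 57,
                            pixels_per_cm = 28.4,
                            resolution = c(1024L, 768L)) {
  stopifnot(is.numeric(viewing_distance_cm), length(viewing_distance_cm) == 1,
            is.numeric(pixels_per_cm), length(pixels_per_cm) == 1,
            is.numeric(resolution), length(resolution) == 2)
  if (viewing_distance_cm <= 0 || pixels_per_cm <= 0 || any(resolution <= 0)) {
    abort("screen geometry parameters must be strictly positive")
  }
  structure(
    list(viewing_distance_cm = viewing_distance_cm,
         pixels_per_cm = pixels_per_cm,
         resolution = as.numeric(resolution)),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %g x %g px, %g px/cm, viewing distance %g cm\n",
              x$resolution[1], x$resolution[2], x$pixels_per_cm,
              x$viewing_distance_cm))
  invisible(x)
}

#' Convert screen pixel coordinates to degrees of visual angle
#'
#' Pixel coordinates use the display convention: origin at the top-left
#' corner, x rightward, y downward, with the screen center at
#' `resolution / 2`. Degrees use the gaze convention: origin at screen
#' center, +x rightward, +y upward. Each axis is converted independently via
#' `atan(offset_cm / viewing_distance_cm)`.
#'
#' @param data Data frame with numeric columns `x` and `y` (pixels).
#' @param geom A [screen_geometry()].
#' @return A tibble with columns `x` and `y` in degrees.
#' @seealso [degrees_to_pixels()] for the exact inverse.
#' @export
pixels_to_degrees <- function(data, geom) {
  stopifnot(inherits(geom, "screen_geometry"))
  data <- as.data.frame(data)
  cx <- geom$resolution[1] / 2
  cy <- geom$resolution[2] / 2
  dx_cm <- (data$x - cx) / geom$pixels_per_cm
  dy_cm <- (data$y - cy) / geom$pixels_per_cm
  tibble::tibble(
    x = atan(dx_cm / geom$viewing_distance_cm) * 180 / pi,
    y = -atan(dy_cm / geom$viewing_distance_cm) * 180 / pi
  )
}

#' Convert degrees of visual angle to screen pixel coordinates
#'
#' Exact inverse of [pixels_to_degrees()].
#'
#' @param data Data frame with numeric columns `x` and `y` (degrees).
#' @inheritParams pixels_to_degrees
#' @return A tibble with columns `x` and `y` in pixels.
#' @export
degrees_to_pixels <- function(data, geom) {
  stopifnot(inherits(geom, "screen_geometry"))
  data <- as.data.frame(data)
  cx <- geom$resolution[1] / 2
  cy <- geom$resolution[2] / 2
  d <- geom$viewing_distance_cm
  tibble::tibble(
    x = cx + tan(data$x * pi / 180) * d * geom$pixels_per_cm,
    y = cy - tan(data$y * pi / 180) * d * geom$pixels_per_cm
  )
}
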