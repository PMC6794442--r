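#' Sensor-array geometry
#'
#' Describes one eye's rectangular "retina": a dense array of square pixels
#' ("photoreceptors") onto which the environment is projected through a
#' pinhole. Both eyes use identical geometry, and corresponding pixels in the
#' two arrays share array coordinates (anatomical correspondence).
#'
#' Azimuth is measured in signed degrees of visual angle, negative to the
#' left of the midline. Column `j` (0-based) covers azimuths
#' `[-H/2 + j*p, -H/2 + (j+1)*p]` where `H` is the horizontal span and `p`
#' the pixel pitch; row 0 is the top of the array.
#'
#' @param width_px array width in pixels.
#' @param height_px array height in pixels.
#' @param pixel_deg pixel pitch, degrees of visual angle per pixel.
#' @return An object of class `sensor_geometry` with fields `width_px`,
#'   `height_px`, `pixel_deg` and the derived `horizontal_span` and
#'   `vertical_span` (degrees).
#' @examples
#' g <- sensor_geometry()
#' g$horizontal_span  # 2 degrees
#' @export
sensor_geometry <- function(width_px = 200L, height_px = 40L, pixel_deg = 0.01) {
  stopifnot(width_px >= 1, height_px >= 1, pixel_deg > 0)
  g <- list(
    width_px = as.integer(width_px),
    height_px = as.integer(height_px),
    pixel_deg = pixel_deg,
    horizontal_span = width_px * pixel_deg,
    vertical_span = height_px * pixel_deg
  )
  class(g) <- "sensor_geometry"
  g
}

#' @export
print.sensor_geometry <- function(x, ...) {
  cat(sprintf(
    "<sensor_geometry> %d x %d px, %.3f deg/px (%.2f x %.2f deg)\n",
    x$width_px, x$height_px, x$pixel_deg, x$horizontal_span, x$vertical_span
  ))
  invisible(x)
}

# Azimuth of the left edge of 0-based column j.
.col_left_azimuth <- function(j, geometry) {
  -geometry$horizontal_span / 2 + j * geometry$pixel_deg
}

# 0-based column index whose left edge sits at azimuth a (a must be on the
# pixel grid up to rounding).
.azimuth_to_col <- function(a, geometry) {
  as.integer(round((a + geometry$horizontal_span / 2) / geometry$pixel_deg))
}
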