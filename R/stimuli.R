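#' Scene specification for the simulated stereo environment
#'
#' The environment contains up to three uniformly luminous fronto-parallel
#' surface strips against a dark background: a fixation strip whose fixated
#' (left) edge sits on the midline at a constant depth, a target strip whose
#' depth varies, and an optional reference strip (relative-disparity stage).
#' Every strip is rendered with its left (eccentric) contrast edge at the
#' nominal azimuth and its body extending toward the fovea, so the sensed
#' vertical boundary falls on the receptive-field center of the monocular
#' unit placed at that azimuth.
#'
#' Depth relative to the horopter is parameterized directly as signed
#' disparity in degrees of visual angle: positive = farther than the
#' horopter (uncrossed), negative = nearer (crossed). The displacement is
#' split symmetrically between the eyes: for disparity `d` the strip in the
#' contralateral (left) eye is translated by `-d/2` in azimuth (eccentric
#' for far stimuli in the left visual field) and in the ipsilateral (right)
#' eye by `+d/2` (foveal), and exchanged for near stimuli.
#'
#' @param target_disparity signed disparity of the target strip, degrees.
#' @param target_offset azimuth of the target strip's eccentric edge,
#'   degrees (negative = left visual field).
#' @param reference_disparity signed disparity of the reference strip, or
#'   `NA` for no reference strip.
#' @param reference_offset azimuth of the reference strip's eccentric edge.
#' @param fixation_offset azimuth of the fixation strip's fixated edge.
#' @param fixation_width width of the fixation surface, degrees.
#' @param strip_width width of the target/reference surfaces, degrees.
#' @param figure_luminance surface luminance, cd/m^2.
#' @param background_luminance background luminance, cd/m^2.
#' @param max_disparity largest admissible |disparity|, degrees (half the
#'   0.36 degree monocular receptive-field width).
#' @return An object of class `scene_spec`.
#' @examples
#' sc <- scene_spec(target_disparity = 0.06)
#' pair <- render_stereo(sc, sensor_geometry())
#' @export
scene_spec <- function(target_disparity = 0,
                       target_offset = -0.3,
                       reference_disparity = NA_real_,
                       reference_offset = -0.6,
                       fixation_offset = 0,
                       fixation_width = 0.3,
                       strip_width = 0.15,
                       figure_luminance = 400,
                       background_luminance = 1,
                       max_disparity = 0.18) {
  if (!is.finite(target_disparity)) stop("target_disparity must be finite")
  if (abs(target_disparity) > max_disparity + 1e-12) {
    stop(sprintf("|target_disparity| = %.4f exceeds max_disparity = %.4f",
                 abs(target_disparity), max_disparity))
  }
  if (!is.na(reference_disparity) && abs(reference_disparity) > max_disparity + 1e-12) {
    stop("|reference_disparity| exceeds max_disparity")
  }
  if (figure_luminance <= background_luminance) {
    stop("figure_luminance must exceed background_luminance")
  }
  if (background_luminance < 0) stop("negative luminance rejected")
  if (strip_width <= 0 || fixation_width <= 0) stop("strip widths must be positive")
  sc <- list(
    target_disparity = target_disparity,
    target_offset = target_offset,
    reference_disparity = reference_disparity,
    reference_offset = reference_offset,
    fixation_offset = fixation_offset,
    fixation_width = fixation_width,
    strip_width = strip_width,
    figure_luminance = figure_luminance,
    background_luminance = background_luminance,
    max_disparity = max_disparity
  )
  class(sc) <- "scene_spec"
  sc
}

# Strip intervals [start, end] (azimuth, degrees) for one eye.
# eye: "contralateral" (left) or "ipsilateral" (right).
# A strip at signed disparity d is translated by -d/2 in the contralateral
# eye and +d/2 in the ipsilateral eye; the fixation strip never moves.
.scene_strips <- function(scene, eye = c("contralateral", "ipsilateral")) {
  eye <- match.arg(eye)
  s <- if (eye == "contralateral") -0.5 else +0.5
  starts <- scene$fixation_offset
  ends <- scene$fixation_offset + scene$fixation_width
  sh <- s * scene$target_disparity
  starts <- c(starts, scene$target_offset + sh)
  ends <- c(ends, scene$target_offset + scene$strip_width + sh)
  if (!is.na(scene$reference_disparity)) {
    sh <- s * scene$reference_disparity
    starts <- c(starts, scene$reference_offset + sh)
    ends <- c(ends, scene$reference_offset + scene$strip_width + sh)
  }
  cbind(start = starts, end = ends)
}

# Length of the overlap of [a0,a1] with [b0,b1]; vectorized.
.overlap_len <- function(a0, a1, b0, b1) {
  pmax(0, pmin(a1, b1) - pmax(a0, b0))
}

# Fraction of the window [x0, x1] covered by the union of intervals.
# starts/ends: either plain vectors (one interval set) or lists of equal-
# length vectors (one interval per strip, vectorized over stimuli).
# Inclusion-exclusion over at most three strips; pairwise intersections of
# intervals are intervals, so the formula is exact.
.union_coverage <- function(starts, ends, x0, x1) {
  if (!is.list(starts)) {
    starts <- as.list(starts)
    ends <- as.list(ends)
  }
  k <- length(starts)
  total <- 0
  for (i in seq_len(k)) {
    total <- total + .overlap_len(starts[[i]], ends[[i]], x0, x1)
  }
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        total <- total - .overlap_len(
          pmax(starts[[i]], starts[[j]]), pmin(ends[[i]], ends[[j]]), x0, x1
        )
      }
    }
  }
  if (k >= 3) {
    total <- total + .overlap_len(
      pmax(starts[[1]], starts[[2]], starts[[3]]),
      pmin(ends[[1]], ends[[2]], ends[[3]]), x0, x1
    )
  }
  frac <- total / (x1 - x0)
  # snap coverage that is an integer up to floating-point dust, so edges
  # meant to fall on pixel boundaries yield exactly binary images
  snap <- abs(frac - round(frac)) < 1e-9
  frac[snap] <- round(frac[snap])
  frac
}

# Luminance profile (one value per column) for one eye of a scene.
.eye_profile <- function(scene, geometry, eye) {
  strips <- .scene_strips(scene, eye)
  half <- geometry$horizontal_span / 2
  if (any(strips[, "start"] < -half - 1e-9) || any(strips[, "end"] > half + 1e-9)) {
    stop("displaced strip edge outside the sensor span")
  }
  x0 <- .col_left_azimuth(seq_len(geometry$width_px) - 1L, geometry)
  frac <- .union_coverage(
    as.list(strips[, 1]), as.list(strips[, 2]), x0, x0 + geometry$pixel_deg
  )
  scene$background_luminance +
    (scene$figure_luminance - scene$background_luminance) * frac
}

#' Render a stereo pair of sensor-array images
#'
#' Projects the scene onto the two sensor arrays. The fixation strip is
#' rendered identically in both eyes; depth-varying strips are displaced by
#' half the disparity in each eye with opposite signs (see [scene_spec()]).
#' Sub-pixel edge positions are rendered by area-weighted anti-aliasing of
#' the edge column, so disparity is continuous despite the pixel grid.
#'
#' @param scene a [scene_spec()].
#' @param geometry a [sensor_geometry()].
#' @return An object of class `stereo_pair`: list with luminance matrices
#'   `left` and `right` (rows x columns, row 1 = top), the scene's
#'   disparities, `relative_disparity` (target minus reference, `NA` without
#'   a reference strip), the luminance levels, and `eye_labels` mapping
#'   contralateral/ipsilateral to left/right (left visual-field convention:
#'   the left eye is contralateral to the processing hemisphere).
#' @examples
#' pair <- render_stereo(scene_spec(target_disparity = 0.04), sensor_geometry())
#' identical(dim(pair$left), dim(pair$right))
#' @export
render_stereo <- function(scene, geometry = sensor_geometry()) {
  stopifnot(inherits(scene, "scene_spec"), inherits(geometry, "sensor_geometry"))
  left <- .eye_profile(scene, geometry, "contralateral")
  right <- .eye_profile(scene, geometry, "ipsilateral")
  pair <- list(
    left = matrix(left, nrow = geometry$height_px, ncol = geometry$width_px,
                  byrow = TRUE),
    right = matrix(right, nrow = geometry$height_px, ncol = geometry$width_px,
                   byrow = TRUE),
    target_disparity = scene$target_disparity,
    reference_disparity = scene$reference_disparity,
    relative_disparity = if (is.na(scene$reference_disparity)) NA_real_ else
      scene$target_disparity - scene$reference_disparity,
    figure_luminance = scene$figure_luminance,
    background_luminance = scene$background_luminance,
    eye_labels = c(contralateral = "left", ipsilateral = "right"),
    geometry = geometry,
    scene = scene
  )
  class(pair) <- "stereo_pair"
  pair
}

#' @export
print.stereo_pair <- function(x, ...) {
  cat(sprintf(
    "<stereo_pair> %d x %d px; target %+0.3f deg%s\n",
    nrow(x$left), ncol(x$left), x$target_disparity,
    if (is.na(x$reference_disparity)) "" else
      sprintf(", reference %+0.3f deg (relative %+0.3f)",
              x$reference_disparity, x$relative_disparity)
  ))
  invisible(x)
}

#' Contrast-invert one eye of a binary stereo pair
#'
#' Produces an anti-correlated stereogram: every figure pixel of the chosen
#' eye becomes background luminance and vice versa; the other eye and the
#' ground-truth disparity labels are untouched. Restricted to pairs rendered
#' with exactly the two luminance levels (whole-pixel edge positions), so
#' the swap is well defined.
#'
#' Applying the operation twice to the same eye restores the original pair.
#'
#' @param pair a [render_stereo()] stereo pair with binary images.
#' @param eye which eye to invert, by anatomical label.
#' @return The modified `stereo_pair`, with attribute-like field
#'   `anticorrelated_eye` recording the inversion (cleared when undone).
#' @export
anticorrelate <- function(pair, eye = c("contralateral", "ipsilateral")) {
  stopifnot(inherits(pair, "stereo_pair"))
  eye <- match.arg(eye)
  side <- pair$eye_labels[[eye]]
  img <- pair[[side]]
  levels <- sort(unique(as.vector(img)))
  allowed <- c(pair$background_luminance, pair$figure_luminance)
  if (length(levels) > 2 || !all(levels %in% allowed)) {
    stop("anticorrelate requires a binary image with exactly the two scene luminance levels")
  }
  out <- img
  out[img == pair$figure_luminance] <- pair$background_luminance
  out[img == pair$background_luminance] <- pair$figure_luminance
  pair[[side]] <- out
  prev <- pair$anticorrelated_eye
  pair$anticorrelated_eye <- if (identical(prev, eye)) NULL else eye
  pair
}
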