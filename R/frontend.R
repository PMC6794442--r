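#' Sigmoid transfer parameters
#'
#' Every connection in the model — the preset subregion and output sigmoids
#' of the monocular units and the evolvable connections onto binocular
#' units — is a scaled logistic `Post = sign * A / (1 + exp(-B * Pre + C))`.
#' `A` is the output gain (non-negative), `B` the slope, `C` the offset, and
#' the discrete `sign` makes the connection excitatory (+1) or inhibitory
#' (-1), so excitation versus inhibition is well defined rather than folded
#' into a negative gain.
#'
#' @param A gain, `A >= 0`.
#' @param B slope.
#' @param C offset.
#' @param sign `+1` or `-1`.
#' @return An object of class `sigmoid_params`.
#' @export
sigmoid_params <- function(A, B, C, sign = 1) {
  stopifnot(is.finite(A), is.finite(B), is.finite(C), A >= 0, sign %in% c(-1, 1))
  p <- list(A = A, B = B, C = C, sign = sign)
  class(p) <- "sigmoid_params"
  p
}

#' Evaluate the sigmoid transfer function
#'
#' `logistic(pre, p)` returns `p$sign * p$A / (1 + exp(-p$B * pre + p$C))`,
#' bounded in `[-A, A]` and monotone in `pre` for positive `B`. At
#' `pre = C/B` the output is `sign * A / 2` (the logistic midpoint).
#'
#' @param pre input drive (any numeric vector; must be finite).
#' @param p a [sigmoid_params()].
#' @return Numeric vector of the same length as `pre`.
#' @examples
#' out <- default_output_params()
#' logistic(0, out)  # 0.9771 / (1 + exp(1.73)) ~ 0.1471
#' @export
logistic <- function(pre, p) {
  if (any(!is.finite(pre))) stop("non-finite input to logistic")
  p$sign * p$A / (1 + exp(p$C - p$B * pre))
}

#' Preset output sigmoid of the monocular units
#' @return The fixed output-stage [sigmoid_params()] (A 0.9771, B 5.7152,
#'   C 1.7300, excitatory).
#' @export
default_output_params <- function() sigmoid_params(0.9771, 5.7152, 1.7300, 1)

#' Preset subregion sigmoids of the monocular units
#'
#' Nine parameter sets in row-major block order for the 3 x 3 subregion
#' grid: the center block (row 2, column 2) is ON (excitatory), the eight
#' surround blocks OFF (inhibitory). The surround gain defaults to 1/8 so
#' total surround inhibition balances the center excitation, the standard
#' center-surround balance; all values are configurable so alternative
#' presets can be dropped in.
#'
#' @param center_A,surround_A gains of the ON center and each OFF block.
#' @param B,C shared slope and offset.
#' @return List of 9 [sigmoid_params()], row-major over the block grid.
#' @export
default_subregion_params <- function(center_A = 1, surround_A = 0.125,
                                     B = 6, C = 1.5) {
  lapply(seq_len(9), function(k) {
    if (k == 5) sigmoid_params(center_A, B, C, 1)
    else sigmoid_params(surround_A, B, C, -1)
  })
}

#' A fixed monocular center-surround unit
#'
#' An ON-center unit with eight OFF subregions: a 3 x 3 grid of 12 x 12
#' pixel blocks, 36 x 36 pixels in total (0.36 x 0.36 degrees at the
#' default pixel pitch), centered on `center_azimuth` with its vertical
#' center at the array midline. The average luminance in each block,
#' normalized by the figure luminance, drives that block's preset sigmoid;
#' the final output sigmoid compiles the sum of the nine transforms into
#' the unit's scalar activity. The unit does not evolve.
#'
#' @param center_azimuth azimuth of the receptive-field center, degrees.
#' @param geometry the [sensor_geometry()] the unit is placed on.
#' @param subregion_params list of 9 [sigmoid_params()] (row-major blocks).
#' @param output_params the output [sigmoid_params()].
#' @param center_row optional 1-based center row; default array midline.
#' @param block_px block side, pixels.
#' @return An object of class `monocular_unit`.
#' @export
monocular_unit <- function(center_azimuth, geometry = sensor_geometry(),
                           subregion_params = default_subregion_params(),
                           output_params = default_output_params(),
                           center_row = NULL, block_px = 12L) {
  stopifnot(length(subregion_params) == 9)
  field_px <- 3L * block_px
  c0 <- .azimuth_to_col(center_azimuth, geometry)      # 0-based
  cols <- (c0 - field_px %/% 2L):(c0 + field_px %/% 2L - 1L) + 1L  # 1-based
  if (cols[1] < 1 || cols[length(cols)] > geometry$width_px) {
    stop("receptive field extends outside the sensor array")
  }
  if (is.null(center_row)) center_row <- geometry$height_px / 2
  r0 <- as.integer(round(center_row - field_px / 2))
  rows <- (r0 + 1L):(r0 + field_px)
  if (rows[1] < 1 || rows[length(rows)] > geometry$height_px) {
    stop("receptive field extends outside the sensor array")
  }
  u <- list(
    center_azimuth = center_azimuth,
    geometry = geometry,
    block_px = as.integer(block_px),
    field_px = field_px,
    rows = rows, cols = cols,
    subregion_params = subregion_params,
    output_params = output_params
  )
  class(u) <- "monocular_unit"
  u
}

#' @export
print.monocular_unit <- function(x, ...) {
  cat(sprintf("<monocular_unit> center %+0.2f deg, field %.2f deg (%d px)\n",
              x$center_azimuth, receptive_field_span(x), x$field_px))
  invisible(x)
}

#' Angular span of a monocular receptive field
#' @param unit a [monocular_unit()].
#' @return Span in degrees (36 px x 0.01 deg/px = 0.36 by default).
#' @export
receptive_field_span <- function(unit) {
  unit$field_px * unit$geometry$pixel_deg
}

#' Normalized mean luminance of a subregion block
#'
#' The drive into a subregion sigmoid: the mean luminance within the block,
#' divided by the figure luminance so a fully illuminated block drives 1.
#'
#' @param image luminance matrix (rows x columns).
#' @param block list with integer vectors `rows` and `cols` (1-based).
#' @param figure_luminance normalizing luminance, cd/m^2.
#' @return Scalar drive in `[0, 1]` for in-range luminances.
#' @export
subregion_drive <- function(image, block, figure_luminance = 400) {
  if (min(block$rows) < 1 || max(block$rows) > nrow(image) ||
      min(block$cols) < 1 || max(block$cols) > ncol(image)) {
    stop("subregion block out of image bounds")
  }
  mean(image[block$rows, block$cols]) / figure_luminance
}

# 1-based row/col ranges of block (r, c) in the 3 x 3 grid, r/c in 1:3.
.unit_block <- function(unit, r, c) {
  b <- unit$block_px
  list(
    rows = unit$rows[((r - 1L) * b + 1L):(r * b)],
    cols = unit$cols[((c - 1L) * b + 1L):(c * b)]
  )
}

#' Activity of a monocular unit on one image
#'
#' Sums the nine subregion sigmoid transforms and passes the sum through
#' the output sigmoid. Deterministic; bounded in `[0, A_out]`.
#'
#' @param image luminance matrix covering the unit's field.
#' @param unit a [monocular_unit()].
#' @param figure_luminance normalizing luminance for the subregion drives.
#' @return Scalar activity.
#' @export
monocular_response <- function(image, unit, figure_luminance = 400) {
  pre <- 0
  for (r in 1:3) for (c in 1:3) {
    k <- (r - 1L) * 3L + c
    d <- subregion_drive(image, .unit_block(unit, r, c), figure_luminance)
    pre <- pre + logistic(d, unit$subregion_params[[k]])
  }
  logistic(pre, unit$output_params)
}

#' Paired monocular units at anatomically corresponding positions
#'
#' Places one monocular unit per retinotopic position in each eye at
#' identical array coordinates (anatomical correspondence), 0.3 degrees
#' apart: fixation (0.0) and target (-0.3) for the absolute-disparity
#' stage, plus reference (-0.6) for the relative stage.
#'
#' @param geometry a [sensor_geometry()].
#' @param stage `"absolute"` (2 pairs) or `"relative"` (3 pairs).
#' @param subregion_params,output_params preset unit parameters, shared by
#'   all units.
#' @return An object of class `monocular_assembly` with fields `stage`,
#'   `positions` (named azimuths) and `units` (one unit per position; the
#'   same unit serves both eyes since the coordinates are identical).
#' @export
place_monocular_pairs <- function(geometry = sensor_geometry(),
                                  stage = c("absolute", "relative"),
                                  subregion_params = default_subregion_params(),
                                  output_params = default_output_params()) {
  stage <- match.arg(stage)
  positions <- if (stage == "absolute") {
    c(fixation = 0, target = -0.3)
  } else {
    c(fixation = 0, target = -0.3, reference = -0.6)
  }
  units <- lapply(positions, monocular_unit, geometry = geometry,
                  subregion_params = subregion_params,
                  output_params = output_params)
  a <- list(stage = stage, positions = positions, units = units,
            geometry = geometry)
  class(a) <- "monocular_assembly"
  a
}

#' @export
print.monocular_assembly <- function(x, ...) {
  cat(sprintf("<monocular_assembly> stage '%s': pairs at %s deg\n",
              x$stage, paste(sprintf("%+0.1f", x$positions), collapse = ", ")))
  invisible(x)
}

#' Pooled receptive-field extent of the depth-comparing stage
#'
#' Width of the union of the monocular receptive fields at the
#' disparity-bearing positions (target and, when present, reference); the
#' fixation field is excluded. For the relative stage this is the 0.66
#' degree pooled field of a third-order unit (fields at -0.3 and -0.6
#' degrees, each 0.36 degrees wide, overlapping by 0.06).
#'
#' @param assembly a [place_monocular_pairs()] assembly.
#' @return Extent in degrees.
#' @export
pooled_field_extent <- function(assembly) {
  pos <- assembly$positions[setdiff(names(assembly$positions), "fixation")]
  half <- receptive_field_span(assembly$units[[2]]) / 2
  ivs <- cbind(pos - half, pos + half)
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
  total <- 0; cur_lo <- ivs[1, 1]; cur_hi <- ivs[1, 2]
  for (i in seq_len(nrow(ivs))[-1]) {
    if (ivs[i, 1] <= cur_hi) cur_hi <- max(cur_hi, ivs[i, 2])
    else { total <- total + (cur_hi - cur_lo); cur_lo <- ivs[i, 1]; cur_hi <- ivs[i, 2] }
  }
  unname(total + (cur_hi - cur_lo))
}

#' Monocular activities of an assembly on one stereo pair
#'
#' @param pair a [render_stereo()] `stereo_pair`.
#' @param assembly a [place_monocular_pairs()] assembly.
#' @return Matrix `positions x eyes` with columns `contralateral` (left
#'   image) and `ipsilateral` (right image).
#' @export
pair_activities <- function(pair, assembly) {
  fig <- pair$figure_luminance
  out <- sapply(c(contralateral = "left", ipsilateral = "right"), function(side) {
    vapply(assembly$units, function(u) monocular_response(pair[[side]], u, fig),
           numeric(1))
  })
  rownames(out) <- names(assembly$positions)
  out
}

# --- fast vectorized activity path ------------------------------------------
# Scenes in a bank are vertically uniform (strips span the full array
# height), so within a unit's field the three blocks of a column group share
# one drive. Activities for a whole bank are computed analytically from the
# strip intervals, bit-equivalent to rendering each pair and applying
# monocular_response (verified in the tests to 1e-12).

# Drives for the 3 column groups of `unit`, vectorized over stimuli.
# starts/ends: lists of per-strip azimuth vectors for one eye.
.unit_column_drives <- function(unit, starts, ends, fig, bg) {
  a <- unit$center_azimuth
  w <- unit$block_px * unit$geometry$pixel_deg
  lapply(1:3, function(g) {
    x0 <- a - 1.5 * w + (g - 1) * w
    frac <- .union_coverage(starts, ends, x0, x0 + w)
    (bg + (fig - bg) * frac) / fig
  })
}

.unit_activity_from_drives <- function(unit, drives) {
  pre <- 0
  for (r in 1:3) for (c in 1:3) {
    k <- (r - 1L) * 3L + c
    pre <- pre + logistic(drives[[c]], unit$subregion_params[[k]])
  }
  logistic(pre, unit$output_params)
}

#' Monocular activities of an assembly across a whole bank
#'
#' Vectorized equivalent of rendering every pair and calling
#' [pair_activities()]: returns an array `stimuli x positions x eyes`.
#'
#' @param bank a `stimulus_bank`.
#' @param assembly a [place_monocular_pairs()] assembly.
#' @return Numeric array with dimensions `c(n, positions, 2)` and eye slices
#'   `contralateral`, `ipsilateral`.
#' @export
bank_activities <- function(bank, assembly) {
  sc <- bank$scenes
  d <- .scene_defaults(bank$params)
  fig <- d$figure_luminance; bg <- d$background_luminance
  w <- d$strip_width
  n <- bank$n
  has_ref <- "reference_disparity" %in% names(sc)
  out <- array(NA_real_, dim = c(n, length(assembly$positions), 2),
               dimnames = list(NULL, names(assembly$positions),
                               c("contralateral", "ipsilateral")))
  for (eye in 1:2) {
    s <- if (eye == 1) -0.5 else +0.5
    starts <- list(rep(0, n), sc$target_offset + s * sc$target_disparity)
    ends <- list(rep(0.3, n), starts[[2]] + w)
    if (has_ref) {
      starts[[3]] <- sc$reference_offset + s * sc$reference_disparity
      ends[[3]] <- starts[[3]] + w
    }
    for (u in seq_along(assembly$units)) {
      drv <- .unit_column_drives(assembly$units[[u]], starts, ends, fig, bg)
      out[, u, eye] <- .unit_activity_from_drives(assembly$units[[u]], drv)
    }
  }
  out
}
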