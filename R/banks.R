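# Stimulus banks: seeded, serializable collections of stereo scenes used as
# the "lifetime" experience of an evolving network. Banks store scene
# parameters (edge positions and disparities), not pixel arrays; pairs are
# rendered on demand, which keeps regeneration bit-identical and cheap.

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so bank generation never perturbs it.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.new_bank <- function(kind, scenes, labels, seed, params,
                      geometry = sensor_geometry()) {
  stopifnot(nrow(scenes) == length(labels))
  b <- list(
    kind = kind,
    n = nrow(scenes),
    seed = seed,
    params = params,
    scenes = scenes,
    labels = labels,
    geometry = geometry
  )
  class(b) <- "stimulus_bank"
  b
}

#' @export
print.stimulus_bank <- function(x, ...) {
  cat(sprintf("<stimulus_bank> kind '%s', %d pairs, seed %s\n",
              x$kind, x$n, format(x$seed)))
  invisible(x)
}

.scene_defaults <- function(params) {
  list(
    strip_width = params$strip_width %||% 0.15,
    figure_luminance = params$figure_luminance %||% 400,
    background_luminance = params$background_luminance %||% 1,
    max_disparity = params$max_disparity %||% 0.18
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract one rendered stereo pair from a bank
#'
#' @param bank a stimulus bank.
#' @param i pair index (1-based).
#' @return A [render_stereo()] `stereo_pair`.
#' @export
bank_pair <- function(bank, i) {
  stopifnot(inherits(bank, "stimulus_bank"), i >= 1, i <= bank$n)
  render_stereo(bank_scene(bank, i), bank$geometry)
}

#' Scene specification of one bank entry
#' @inheritParams bank_pair
#' @return A [scene_spec()].
#' @export
bank_scene <- function(bank, i) {
  row <- bank$scenes[i, ]
  d <- .scene_defaults(bank$params)
  scene_spec(
    target_disparity = row$target_disparity,
    target_offset = row$target_offset,
    reference_disparity = if ("reference_disparity" %in% names(row))
      row$reference_disparity else NA_real_,
    reference_offset = if ("reference_offset" %in% names(row) &&
                           !is.na(row$reference_offset))
      row$reference_offset else -0.6,
    strip_width = d$strip_width,
    figure_luminance = d$figure_luminance,
    background_luminance = d$background_luminance,
    max_disparity = d$max_disparity
  )
}

#' Bank of absolute-disparity training stimuli
#'
#' Disparity magnitudes are drawn uniformly on `(0, max_disparity]` with the
#' sign fixed by `polarity` ("far" = uncrossed, positive; "near" = crossed,
#' negative). Networks that discriminate far surfaces are evolved separately
#' from near ones, so a bank carries a single polarity. Labels are the
#' signed absolute disparities in degrees.
#'
#' @param n number of stimuli (one network lifetime is 200).
#' @param polarity `"far"` or `"near"`.
#' @param max_disparity largest |disparity|, degrees; default 0.18, half the
#'   0.36 degree receptive-field width.
#' @param seed integer seed; regeneration from the same arguments is
#'   bit-identical.
#' @param target_offset azimuth of the target strip edge, degrees.
#' @param strip_width surface strip width, degrees.
#' @return A `stimulus_bank` of kind `absolute_far` or `absolute_near`.
#' @examples
#' b <- make_absolute_bank(10, "far", seed = 1)
#' all(b$labels > 0)
#' @export
make_absolute_bank <- function(n, polarity = c("far", "near"),
                               max_disparity = 0.18, seed = 1L,
                               target_offset = -0.3, strip_width = 0.15) {
  polarity <- match.arg(polarity)
  stopifnot(n >= 1, max_disparity > 0, max_disparity <= 0.18)
  sgn <- if (polarity == "far") 1 else -1
  mag <- .with_seed(seed, max_disparity * (1 - runif(n)))  # (0, max]
  scenes <- data.frame(
    target_offset = rep(target_offset, n),
    target_disparity = sgn * mag
  )
  .new_bank(
    kind = paste0("absolute_", polarity),
    scenes = scenes, labels = sgn * mag, seed = seed,
    params = list(polarity = polarity, max_disparity = max_disparity,
                  target_offset = target_offset, strip_width = strip_width)
  )
}

#' Bank of relative-disparity training stimuli
#'
#' Target and reference disparities are drawn independently and uniformly on
#' `[-max_disparity, max_disparity]`, then rejection-sampled so the relative
#' disparity (target minus reference) has the sign required by `polarity`
#' (`"rel_far"` = positive, `"rel_near"` = negative). All three surface
#' configurations therefore occur: both farther than the horopter, both
#' nearer, and straddling it, with expected frequencies 1/4, 1/4, 1/2.
#' Labels are the signed relative disparities.
#'
#' @inheritParams make_absolute_bank
#' @param polarity `"rel_far"` or `"rel_near"`.
#' @param reference_offset azimuth of the reference strip edge, degrees.
#' @return A `stimulus_bank` of kind `relative`.
#' @export
make_relative_bank <- function(n, max_disparity = 0.18,
                               polarity = c("rel_far", "rel_near"),
                               seed = 1L, target_offset = -0.3,
                               reference_offset = -0.6, strip_width = 0.15) {
  polarity <- match.arg(polarity)
  stopifnot(n >= 1, max_disparity > 0, max_disparity <= 0.18)
  sgn <- if (polarity == "rel_far") 1 else -1
  draws <- .with_seed(seed, {
    t_d <- numeric(0); r_d <- numeric(0)
    while (length(t_d) < n) {
      m <- 2L * (n - length(t_d)) + 8L
      tt <- runif(m, -max_disparity, max_disparity)
      rr <- runif(m, -max_disparity, max_disparity)
      keep <- sign(tt - rr) == sgn
      t_d <- c(t_d, tt[keep]); r_d <- c(r_d, rr[keep])
    }
    list(t = t_d[seq_len(n)], r = r_d[seq_len(n)])
  })
  scenes <- data.frame(
    target_offset = rep(target_offset, n),
    target_disparity = draws$t,
    reference_offset = rep(reference_offset, n),
    reference_disparity = draws$r
  )
  .new_bank(
    kind = "relative",
    scenes = scenes, labels = draws$t - draws$r, seed = seed,
    params = list(polarity = polarity, max_disparity = max_disparity,
                  target_offset = target_offset,
                  reference_offset = reference_offset,
                  strip_width = strip_width)
  )
}

#' Classify relative-disparity configurations
#'
#' @param bank a relative `stimulus_bank`.
#' @return Factor with levels `both_far`, `straddle`, `both_near`.
#' @export
relative_classes <- function(bank) {
  stopifnot(bank$kind == "relative")
  t_d <- bank$scenes$target_disparity
  r_d <- bank$scenes$reference_disparity
  cls <- ifelse(t_d > 0 & r_d > 0, "both_far",
                ifelse(t_d < 0 & r_d < 0, "both_near", "straddle"))
  factor(cls, levels = c("both_far", "straddle", "both_near"))
}

#' Position-randomized control bank
#'
#' Like [make_absolute_bank()] but the target strip azimuth is drawn
#' uniformly over the range whose displaced edges stay at least `margin`
#' degrees from the array borders, destroying the fixed retinotopic
#' relationship between the stimulus and the monocular units. Labels remain
#' the signed absolute disparities.
#'
#' @inheritParams make_absolute_bank
#' @param margin minimum distance of any displaced edge from the array
#'   border, degrees.
#' @param geometry sensor geometry used to derive legal offsets.
#' @return A `stimulus_bank` of kind `control`.
#' @export
make_control_bank <- function(n, max_disparity = 0.18, seed = 1L,
                              polarity = c("far", "near"),
                              margin = 0.18, strip_width = 0.15,
                              geometry = sensor_geometry()) {
  polarity <- match.arg(polarity)
  stopifnot(n >= 1, max_disparity > 0, max_disparity <= 0.18)
  half <- geometry$horizontal_span / 2
  lo <- -half + margin + max_disparity / 2
  hi <- half - margin - strip_width - max_disparity / 2
  stopifnot(lo < hi)
  sgn <- if (polarity == "far") 1 else -1
  draws <- .with_seed(seed, list(
    mag = max_disparity * (1 - runif(n)),
    off = runif(n, lo, hi)
  ))
  scenes <- data.frame(
    target_offset = draws$off,
    target_disparity = sgn * draws$mag
  )
  .new_bank(
    kind = "control",
    scenes = scenes, labels = sgn * draws$mag, seed = seed,
    params = list(polarity = polarity, max_disparity = max_disparity,
                  strip_width = strip_width, margin = margin,
                  offset_range = c(lo, hi))
  )
}

#' Serialize a stimulus bank to a directory
#'
#' Writes a JSON manifest (kind, parameters, seed, labels), a CSV of scene
#' edge positions for lightweight replay and, optionally, one plain-text CSV
#' luminance matrix per rendered pair and eye (row-major, row 1 = top).
#'
#' @param bank the bank.
#' @param dir output directory (created if absent).
#' @param images also write rendered pixel arrays.
#' @return `dir`, invisibly.
#' @export
write_bank <- function(bank, dir, images = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    kind = bank$kind, n = bank$n, seed = bank$seed, params = bank$params,
    labels = bank$labels,
    geometry = unclass(bank$geometry)[c("width_px", "height_px", "pixel_deg")]
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(bank$scenes, file.path(dir, "scenes.csv"), row.names = FALSE)
  if (images) {
    for (i in seq_len(bank$n)) {
      p <- bank_pair(bank, i)
      utils::write.table(p$left, file.path(dir, sprintf("pair_%03d_left.csv", i)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
      utils::write.table(p$right, file.path(dir, sprintf("pair_%03d_right.csv", i)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read a stimulus bank written by [write_bank()]
#' @param dir directory containing `manifest.json` and `scenes.csv`.
#' @return A `stimulus_bank`.
#' @export
read_bank <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  scenes <- utils::read.csv(file.path(dir, "scenes.csv"))
  g <- manifest$geometry
  .new_bank(
    kind = manifest$kind, scenes = scenes, labels = manifest$labels,
    seed = manifest$seed, params = as.list(manifest$params),
    geometry = sensor_geometry(g$width_px, g$height_px, g$pixel_deg)
  )
}
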