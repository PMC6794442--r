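# Independent scalar reference implementations used as oracles. They follow
# the documented conventions directly (per-pixel loops, explicit formulas)
# and share no code with the package's vectorized paths.

# Strip intervals for one eye under the documented convention: each strip's
# eccentric (left) edge at its nominal azimuth, body extending foveally;
# depth-bearing strips translated by -d/2 (contralateral/left eye) or +d/2
# (ipsilateral/right eye).
oracle_strips <- function(scene, eye) {
  s <- if (eye == "contralateral") -0.5 else 0.5
  iv <- list(c(scene$fixation_offset,
               scene$fixation_offset + scene$fixation_width))
  sh <- s * scene$target_disparity
  iv[[2]] <- c(scene$target_offset + sh,
               scene$target_offset + scene$strip_width + sh)
  if (!is.na(scene$reference_disparity)) {
    sh <- s * scene$reference_disparity
    iv[[3]] <- c(scene$reference_offset + sh,
                 scene$reference_offset + scene$strip_width + sh)
  }
  iv
}

# Length of the union of intervals clipped to [x0, x1], by merge of sorted
# intervals.
oracle_union_len <- function(intervals, x0, x1) {
  clipped <- list()
  for (iv in intervals) {
    a <- max(iv[1], x0); b <- min(iv[2], x1)
    if (b > a) clipped[[length(clipped) + 1]] <- c(a, b)
  }
  if (!length(clipped)) return(0)
  o <- order(vapply(clipped, `[`, numeric(1), 1))
  clipped <- clipped[o]
  total <- 0; lo <- clipped[[1]][1]; hi <- clipped[[1]][2]
  for (iv in clipped[-1]) {
    if (iv[1] <= hi) hi <- max(hi, iv[2])
    else { total <- total + hi - lo; lo <- iv[1]; hi <- iv[2] }
  }
  total + hi - lo
}

# Per-pixel scalar renderer.
oracle_render <- function(scene, geometry) {
  out <- list()
  for (eye in c("contralateral", "ipsilateral")) {
    iv <- oracle_strips(scene, eye)
    img <- matrix(NA_real_, geometry$height_px, geometry$width_px)
    for (j in seq_len(geometry$width_px)) {
      x0 <- -geometry$horizontal_span / 2 + (j - 1) * geometry$pixel_deg
      f <- oracle_union_len(iv, x0, x0 + geometry$pixel_deg) / geometry$pixel_deg
      img[, j] <- scene$background_luminance +
        (scene$figure_luminance - scene$background_luminance) * f
    }
    out[[eye]] <- img
  }
  out
}

oracle_logistic <- function(pre, A, B, C, s) s * A / (1 + exp(-B * pre + C))

# Scalar monocular unit: explicit loops over the 3 x 3 blocks and their
# pixels.
oracle_monocular <- function(image, unit, figure_luminance = 400) {
  pre <- 0
  for (r in 1:3) for (c in 1:3) {
    rows <- unit$rows[((r - 1) * unit$block_px + 1):(r * unit$block_px)]
    cols <- unit$cols[((c - 1) * unit$block_px + 1):(c * unit$block_px)]
    tot <- 0
    for (rr in rows) for (cc in cols) tot <- tot + image[rr, cc]
    d <- tot / (length(rows) * length(cols)) / figure_luminance
    p <- unit$subregion_params[[(r - 1) * 3 + c]]
    pre <- pre + oracle_logistic(d, p$A, p$B, p$C, p$sign)
  }
  p <- unit$output_params
  oracle_logistic(pre, p$A, p$B, p$C, p$sign)
}

# Scalar sum-of-sigmoids forward pass on a length-4 input.
oracle_binoc <- function(inputs, genome) {
  tot <- 0
  for (c in 1:4) {
    p <- genome$connections[[c]]
    tot <- tot + oracle_logistic(inputs[c], p$A, p$B, p$C, p$sign)
  }
  tot
}

random_genome_params <- function() {
  lapply(1:4, function(i)
    sigmoid_params(runif(1, 0, 0.5), runif(1, 0, 10), runif(1, -5, 5),
                   sample(c(-1, 1), 1)))
}
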