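test_that("the sigmoid transfer has the documented midpoint and limits", {
  p <- sigmoid_params(A = 0.8, B = 4, C = 1.2, sign = -1)
  expect_equal(logistic(1.2 / 4, p), -0.8 / 2)
  expect_equal(logistic(1e3, p), -0.8)
  expect_equal(logistic(-1e3, p), 0)
  expect_error(logistic(NaN, p), "non-finite")
  expect_error(sigmoid_params(-0.1, 1, 0), "A >= 0")
  expect_error(sigmoid_params(1, 1, 0, sign = 2))
})

test_that("the preset output sigmoid evaluates as printed", {
  out <- default_output_params()
  expect_equal(logistic(0, out), 0.9771 / (1 + exp(1.73)), tolerance = 1e-12)
  expect_equal(round(logistic(0, out), 4), 0.1471)
})

test_that("subregion drives are luminance means normalized by the figure", {
  img <- matrix(400, 40, 200)
  blk <- list(rows = 1:12, cols = 1:12)
  expect_equal(subregion_drive(img, blk), 1)
  img[] <- 1
  expect_equal(subregion_drive(img, blk), 0.0025)
  img[, 1:6] <- 400  # half figure, half background
  expect_equal(subregion_drive(img, blk), 0.50125)
  expect_error(subregion_drive(img, list(rows = 30:41, cols = 1:12)),
               "out of image bounds")
})

test_that("monocular units span 0.36 degrees and respect correspondence", {
  asm <- place_monocular_pairs(stage = "absolute")
  expect_length(asm$units, 2)
  expect_equal(receptive_field_span(asm$units[["target"]]), 0.36)
  pair <- render_stereo(scene_spec(target_disparity = 0))
  act <- pair_activities(pair, asm)
  expect_equal(act[, "contralateral"], act[, "ipsilateral"])
  asm3 <- place_monocular_pairs(stage = "relative")
  expect_length(asm3$units, 3)
  expect_equal(unname(asm3$positions), c(0, -0.3, -0.6))
  expect_equal(pooled_field_extent(asm3), 0.66)
  expect_equal(pooled_field_extent(asm), 0.36)
})

test_that("a swept vertical edge produces a single-peaked activity profile", {
  g <- sensor_geometry()
  u <- monocular_unit(-0.3, g)
  # isolated 15-px strip swept across the field, oracle evaluation
  resp <- vapply(10:120, function(j0) {
    img <- matrix(1, 40, 200)
    img[, j0:(j0 + 14)] <- 400
    oracle_monocular(img, u)
  }, numeric(1))
  k <- which.max(resp)
  # single global peak, rising monotonically from the left (surround-driven)
  # trough and falling monotonically to the right trough
  t1 <- which.min(resp[seq_len(k)])
  t2 <- k - 1 + which.min(resp[k:length(resp)])
  expect_true(all(diff(resp[t1:k]) >= -1e-12))
  expect_true(all(diff(resp[k:t2]) <= 1e-12))
  # peak with the figure over the ON center block (columns 65:76)
  j_peak <- (10:120)[k]
  expect_lt(abs(j_peak + 7 - 70.5), 3.1)
})

test_that("activity is invariant to whole-pixel co-translation of image and unit", {
  g <- sensor_geometry()
  set.seed(42)
  img <- matrix(runif(40 * 200, 1, 400), 40, 200)
  u1 <- monocular_unit(-0.3, g)
  u2 <- monocular_unit(-0.3 + 0.05, g)
  shifted <- cbind(matrix(1, 40, 5), img[, 1:195])
  expect_equal(monocular_response(img, u1), monocular_response(shifted, u2))
})

test_that("vectorized bank activities equal the scalar per-pixel oracle", {
  asm <- place_monocular_pairs(stage = "relative")
  b <- make_relative_bank(20, polarity = "rel_near", seed = 9)
  fast <- bank_activities(b, asm)
  for (i in seq_len(b$n)) {
    pair <- bank_pair(b, i)
    for (u in seq_along(asm$units)) {
      expect_lt(abs(fast[i, u, "contralateral"] -
                    oracle_monocular(pair$left, asm$units[[u]])), 1e-12)
      expect_lt(abs(fast[i, u, "ipsilateral"] -
                    oracle_monocular(pair$right, asm$units[[u]])), 1e-12)
    }
  }
  b2 <- make_absolute_bank(15, "far", seed = 10)
  asm2 <- place_monocular_pairs(stage = "absolute")
  fast2 <- bank_activities(b2, asm2)
  for (i in seq_len(b2$n)) {
    pair <- bank_pair(b2, i)
    for (u in 1:2) {
      expect_lt(abs(fast2[i, u, "contralateral"] -
                    oracle_monocular(pair$left, asm2$units[[u]])), 1e-12)
    }
  }
})

test_that("activities stay finite and bounded by the output gain", {
  asm <- place_monocular_pairs(stage = "absolute")
  b <- make_absolute_bank(50, "near", seed = 12)
  act <- bank_activities(b, asm)
  expect_true(all(is.finite(act)))
  expect_true(all(act >= 0 & act <= default_output_params()$A))
})
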