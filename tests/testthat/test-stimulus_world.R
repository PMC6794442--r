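test_that("zero disparity yields identical images in the two eyes", {
  for (d_ref in c(NA_real_, 0)) {
    pair <- render_stereo(scene_spec(target_disparity = 0,
                                     reference_disparity = d_ref))
    expect_identical(pair$left, pair$right)
  }
})

test_that("the fixation strip occupies 0.3 x 0.4 degrees at figure luminance", {
  pair <- render_stereo(scene_spec())
  # azimuth [0, 0.3] -> 30 columns starting at the midline column
  fix_cols <- 101:130
  expect_true(all(pair$left[, fix_cols] == 400))
  expect_equal(sum(pair$left == 400), (30 + 15) * 40)  # fixation + target strips
  expect_true(all(pair$left[, 1:50] == 1))
})

test_that("disparity displaces the target edges half-and-half across eyes", {
  pair <- render_stereo(scene_spec(target_disparity = 0.04))
  base <- render_stereo(scene_spec(target_disparity = 0))
  # contralateral (left) eye: strip shifted 2 px eccentric (leftward)
  fig_cols <- function(img) which(img[1, ] == 400)
  tgt <- function(img) setdiff(fig_cols(img), 101:130)
  expect_equal(tgt(pair$left), tgt(base$left) - 2)
  expect_equal(tgt(pair$right), tgt(base$right) + 2)
})

test_that("rendering matches the scalar per-pixel oracle, including sub-pixel edges", {
  g <- sensor_geometry()
  for (d in c(-0.113, -0.04, 0.017, 0.0555, 0.18)) {
    for (d_ref in c(NA_real_, 0.061)) {
      sc <- scene_spec(target_disparity = d, reference_disparity = d_ref)
      pair <- render_stereo(sc, g)
      orc <- oracle_render(sc, g)
      expect_lt(max(abs(pair$left - orc$contralateral)), 1e-6)
      expect_lt(max(abs(pair$right - orc$ipsilateral)), 1e-6)
    }
  }
})

test_that("figure area is conserved across eyes for any disparity", {
  for (d in c(-0.17, -0.033, 0.011, 0.09, 0.145)) {
    pair <- render_stereo(scene_spec(target_disparity = d,
                                     reference_disparity = -d / 2))
    expect_equal(sum(pair$left - 1), sum(pair$right - 1), tolerance = 1e-9)
  }
})

test_that("out-of-range scenes are rejected", {
  expect_error(scene_spec(target_disparity = 0.19), "max_disparity")
  expect_error(scene_spec(background_luminance = -1), "luminance")
  expect_error(scene_spec(figure_luminance = 0.5), "exceed")
  # displaced edge pushed outside the array
  expect_error(
    render_stereo(scene_spec(target_disparity = 0.16, target_offset = -0.93)),
    "outside the sensor span")
})

test_that("anticorrelate swaps the two luminance levels in one eye only", {
  pair <- render_stereo(scene_spec(target_disparity = 0.04))
  ac <- anticorrelate(pair, "contralateral")
  expect_identical(ac$right, pair$right)
  expect_true(all(ac$left[pair$left == 400] == 1))
  expect_true(all(ac$left[pair$left == 1] == 400))
  expect_identical(ac$target_disparity, pair$target_disparity)
  # involution
  back <- anticorrelate(ac, "contralateral")
  expect_identical(back$left, pair$left)
  expect_null(back$anticorrelated_eye)
  # anti-aliased (sub-pixel) images are rejected
  aa <- render_stereo(scene_spec(target_disparity = 0.01))
  expect_error(anticorrelate(aa, "contralateral"), "binary")
})

test_that("anticorrelating an eye reverses that eye's monocular modulation", {
  asm <- place_monocular_pairs(stage = "absolute")
  base0 <- pair_activities(render_stereo(scene_spec(target_disparity = 0)), asm)
  base1 <- pair_activities(render_stereo(scene_spec(target_disparity = 0.04)), asm)
  ac0 <- pair_activities(anticorrelate(render_stereo(scene_spec(target_disparity = 0)),
                                       "contralateral"), asm)
  ac1 <- pair_activities(anticorrelate(render_stereo(scene_spec(target_disparity = 0.04)),
                                       "contralateral"), asm)
  conv <- base1["target", "contralateral"] - base0["target", "contralateral"]
  flip <- ac1["target", "contralateral"] - ac0["target", "contralateral"]
  expect_gt(conv, 0)   # far disparity raises contralateral activity
  expect_lt(flip, 0)   # contrast inversion reverses the direction
})

test_that("absolute banks have the requested size, sign and determinism", {
  b <- make_absolute_bank(200, "far", seed = 1)
  expect_equal(b$n, 200)
  expect_true(all(b$labels > 0 & b$labels <= 0.18))
  bn <- make_absolute_bank(50, "near", seed = 2)
  expect_true(all(bn$labels < 0))
  expect_identical(make_absolute_bank(200, "far", seed = 1), b)
  expect_error(make_absolute_bank(10, "sideways"))
})

test_that("relative banks cover the three surface configurations", {
  b <- make_relative_bank(300, polarity = "rel_far", seed = 7)
  expect_equal(b$labels,
               b$scenes$target_disparity - b$scenes$reference_disparity)
  expect_true(all(b$labels > 0))
  cls <- relative_classes(b)
  expect_setequal(levels(cls), c("both_far", "straddle", "both_near"))
  expect_true(all(table(cls) > 0))
  bn <- make_relative_bank(100, polarity = "rel_near", seed = 8)
  expect_true(all(bn$labels < 0))
})

test_that("relative-bank class frequencies match independent rejection sampling", {
  # both-far : straddle : both-near = 1/4 : 1/2 : 1/4 given a positive
  # relative sign (uniform independent disparities)
  b <- make_relative_bank(8000, polarity = "rel_far", seed = 11)
  freq <- as.numeric(table(relative_classes(b))) / 8000
  expect_equal(freq, c(0.25, 0.5, 0.25), tolerance = 0.06)
})

test_that("control banks randomize position within legal bounds, uniformly", {
  b <- make_control_bank(10000, seed = 3)
  lo <- b$params$offset_range[1]; hi <- b$params$offset_range[2]
  expect_true(all(b$scenes$target_offset >= lo & b$scenes$target_offset <= hi))
  expect_identical(make_control_bank(10000, seed = 3), b)
  ks <- suppressWarnings(
    stats::ks.test(b$scenes$target_offset, "punif", lo, hi))
  expect_gt(ks$p.value, 0.01)
  # every rendered pair keeps its edges inside the array
  for (i in c(1, 5000, 10000)) expect_s3_class(bank_pair(b, i), "stereo_pair")
})

test_that("bank serialization round-trips", {
  b <- make_relative_bank(12, polarity = "rel_near", seed = 5)
  dir <- withr::local_tempdir()
  write_bank(b, dir)
  b2 <- read_bank(dir)
  expect_equal(b2$labels, b$labels)
  expect_equal(b2$scenes, b$scenes)
  expect_equal(b2$kind, b$kind)
  expect_equal(bank_pair(b2, 3)$left, bank_pair(b, 3)$left)
})
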