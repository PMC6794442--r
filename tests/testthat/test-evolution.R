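asm_abs <- place_monocular_pairs(stage = "absolute")

test_that("lifetime error is the summed absolute coding error in degrees", {
  fx <- generate_fixtures(seed = 3)
  expect_equal(lifetime_error(fx$genomes$perfect, fx$constant_bank, asm_abs), 0)
  # single-trial bank, constant response 0.05 vs label 0.12
  b1 <- fx$constant_bank
  b1$scenes <- b1$scenes[1, , drop = FALSE]
  b1$labels <- 0.12; b1$n <- 1L
  g05 <- new_genome("second_order", "far", list(
    sigmoid_params(0.1, 0, 0, 1), sigmoid_params(0, 0, 0, 1),
    sigmoid_params(0, 0, 0, 1), sigmoid_params(0, 0, 0, 1)))
  expect_equal(lifetime_error(g05, b1, asm_abs), 0.07)
  expect_error(lifetime_error(fx$genomes$perfect, fx$relative_bank, asm_abs),
               "incompatible")
})

test_that("a constant-zero responder scores the expected uniform-label error", {
  zg <- generate_fixtures(seed = 4)$genomes$zero_gain
  errs <- vapply(1:5, function(s)
    lifetime_error(zg, make_absolute_bank(200, "far", seed = 100 + s), asm_abs),
    numeric(1))
  # labels ~ U(0, 0.18]: expectation 200 * 0.09 = 18, sd ~ 0.73
  expect_lt(abs(mean(errs) - 18), 1.5)
})

test_that("success scores are max-minus-error with a uniform fallback", {
  s <- success_scores(c(0.1, 0.3, 0.6))
  expect_equal(s, c(0.5, 0.3, 0))
  expect_equal(s / sum(s), c(0.625, 0.375, 0))
  expect_equal(success_scores(c(2, 2, 2)), c(1, 1, 1))
  expect_equal(success_scores(5), 1)
  expect_error(success_scores(c(0.2, -0.1)), "negative")
})

test_that("roulette selection is fitness-proportionate and deterministic", {
  set.seed(5)
  expect_true(all(roulette_select(c(1, 0, 0), 500) == 1L))
  set.seed(6)
  draws <- roulette_select(c(2, 1, 1), 1e5)
  freq <- tabulate(draws, 3) / 1e5
  se <- sqrt(c(0.5, 0.25, 0.25) * c(0.5, 0.75, 0.75) / 1e5)
  expect_true(all(abs(freq - c(0.5, 0.25, 0.25)) < 3 * se))
  set.seed(7); a <- roulette_select(c(1, 2, 3), 100)
  set.seed(7); b <- roulette_select(c(1, 2, 3), 100)
  expect_identical(a, b)
  expect_message(roulette_select(c(0, 0), 10), "uniform")
  expect_error(roulette_select(c(-1, 1), 10), "negative")
})

test_that("parameter exchange conserves the population-wide multiset", {
  set.seed(8)
  pop <- replicate(40, init_genome("second_order", "far"), simplify = FALSE)
  col <- function(p) vapply(p, function(g) unlist(lapply(
    g$connections, function(x) c(x$A, x$B, x$C, x$sign))), numeric(16))
  before <- col(pop)
  after <- col(exchange_parameters(pop, 0.8))
  for (r in 1:16) expect_equal(sort(after[r, ]), sort(before[r, ]))
  expect_false(identical(after, before))
  # p = 0 is the identity
  expect_identical(exchange_parameters(pop, 0), pop)
  expect_message(exchange_parameters(pop[1], 0.5), "no-op")
})

test_that("untouched fraction under exchange matches the sampling rule", {
  # an individual stays untouched iff it neither chooses to exchange
  # (prob 1 - p) nor is picked as a partner by any chooser
  set.seed(9)
  n <- 100; p <- 0.8
  pop0 <- matrix(runif(16 * n), 16, n)
  frac <- mean(replicate(300, {
    pop1 <- evostereo:::.exchange_matrix(pop0, p)
    mean(colSums(abs(pop1 - pop0)) == 0)
  }))
  expected <- (1 - p) * ((n - 2) / (n - 1))^(p * n)
  expect_lt(abs(frac - expected), 0.01)
})

test_that("mutation respects bounds and probability 0 is the identity", {
  set.seed(10)
  P <- evostereo:::.init_population_matrix(200)
  expect_identical(evostereo:::.mutate_matrix(P, 0, 0.05), P)
  b <- evostereo:::.param_bounds()
  for (i in 1:20) P <- evostereo:::.mutate_matrix(P, 0.5, 0.2, b)
  expect_true(all(P[1:12, ] >= b$lo) && all(P[1:12, ] <= b$hi))
  expect_true(all(P[13:16, ] %in% c(-1, 1)))
})

test_that("evolution runs are bit-reproducible from the master seed", {
  cfg <- evolution_config(n_populations = 2, population_size = 30,
                          lifetime_stimuli = 40, generations = 5,
                          master_seed = 21, scale = "desk")
  r1 <- evolve_absolute(cfg, "far")
  r2 <- evolve_absolute(cfg, "far")
  expect_identical(r1$traces, r2$traces)
  expect_identical(r1$populations, r2$populations)
  expect_identical(r1$final_errors, r2$final_errors)
})

test_that("zero generations reproduce the random-initialization baseline", {
  cfg <- evolution_config(n_populations = 2, population_size = 50,
                          lifetime_stimuli = 100, generations = 0,
                          master_seed = 13, scale = "desk")
  r <- evolve_absolute(cfg, "near")
  expect_equal(nrow(r$traces), 0)
  mae <- vapply(r$final_errors, mean, numeric(1)) / 100
  expect_gt(min(mae), 0.06)   # far from the evolved < 0.02 regime
  expect_lt(max(mae), 0.2)
})

test_that("population error declines over generations on the retinotopic task", {
  cfg <- evolution_config(n_populations = 1, population_size = 100,
                          lifetime_stimuli = 100, generations = 80,
                          master_seed = 2, scale = "desk")
  r <- evolve_absolute(cfg, "far")
  trace <- r$traces[, 1] / 100
  expect_lt(mean(trace[71:80]), 0.65 * mean(trace[1:10]))
})

test_that("the relative stage requires frozen second-order genomes", {
  cfg <- evolution_config(n_populations = 1, population_size = 10,
                          lifetime_stimuli = 10, generations = 1,
                          master_seed = 1, scale = "desk")
  expect_error(evolve_relative(cfg, "rel_far", second_order = NULL), "frozen")
  set.seed(30)
  so <- list(far = init_genome("second_order", "far"),
             near = init_genome("second_order", "near"))
  r <- evolve_relative(cfg, "rel_near", so)
  expect_s3_class(r, "evo_run")
  expect_equal(r$stage, "third_order")
  expect_identical(r$second_order, so)
})
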