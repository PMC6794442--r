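#' Evolution run configuration
#'
#' Defaults follow the full-scale training regime: 20 independent
#' populations of 500 networks, 200 stimuli per network lifetime, 2,500
#' generations, an 80% chance per individual of parameter exchange, and a
#' small Gaussian mutation (2% per parameter, standard deviation 5% of the
#' parameter's allowed range, clipped to bounds) that lets parameter values
#' absent from the initial population arise. `scale = "desk"` selects the
#' reduced regime used for routine analysis on a single core: 5 populations
#' of 200 networks for 600 generations.
#'
#' @param n_populations independent replicate populations.
#' @param population_size networks per population.
#' @param lifetime_stimuli stimuli per network lifetime (per generation).
#' @param generations number of generations.
#' @param exchange_probability chance an individual undergoes parameter
#'   exchange each generation.
#' @param mutation_probability per-parameter Gaussian mutation chance.
#' @param mutation_scale mutation standard deviation as a fraction of each
#'   parameter's allowed range.
#' @param max_disparity training disparity range, degrees.
#' @param master_seed integer seed; the per-population and per-generation
#'   streams are split from it deterministically.
#' @param scale `"paper"` for the full regime, `"desk"` for the reduced one;
#'   explicit arguments override either.
#' @return An object of class `evolution_config`.
#' @export
evolution_config <- function(n_populations = NULL, population_size = NULL,
                             lifetime_stimuli = NULL, generations = NULL,
                             exchange_probability = 0.8,
                             mutation_probability = 0.02,
                             mutation_scale = 0.05,
                             max_disparity = 0.18,
                             master_seed = 1L,
                             scale = c("paper", "desk")) {
  scale <- match.arg(scale)
  base <- if (scale == "paper") {
    list(n_populations = 20L, population_size = 500L,
         lifetime_stimuli = 200L, generations = 2500L)
  } else {
    list(n_populations = 5L, population_size = 200L,
         lifetime_stimuli = 200L, generations = 600L)
  }
  cfg <- list(
    n_populations = as.integer(n_populations %||% base$n_populations),
    population_size = as.integer(population_size %||% base$population_size),
    lifetime_stimuli = as.integer(lifetime_stimuli %||% base$lifetime_stimuli),
    generations = as.integer(generations %||% base$generations),
    exchange_probability = exchange_probability,
    mutation_probability = mutation_probability,
    mutation_scale = mutation_scale,
    max_disparity = max_disparity,
    master_seed = as.integer(master_seed),
    scale = scale
  )
  with(cfg, stopifnot(
    n_populations >= 1, population_size >= 1, lifetime_stimuli >= 1,
    generations >= 0, exchange_probability >= 0, exchange_probability <= 1,
    mutation_probability >= 0, mutation_probability <= 1,
    max_disparity > 0, max_disparity <= 0.18
  ))
  class(cfg) <- "evolution_config"
  cfg
}

#' @export
print.evolution_config <- function(x, ...) {
  cat(sprintf(
    "<evolution_config> %d pops x %d nets, %d stimuli/lifetime, %d generations (scale '%s', seed %d)\n",
    x$n_populations, x$population_size, x$lifetime_stimuli, x$generations,
    x$scale, x$master_seed))
  invisible(x)
}

# Deterministic seed splitting: integer arithmetic exact in doubles, result
# in [1, 2^31 - 2] so it is a valid 32-bit R seed.
.split_seed <- function(seed, index) {
  as.integer((abs(seed) * 48271 + index * 1299721) %% 2147483399 + 1)
}

#' Lifetime error of one genome on a bank
#'
#' The summed absolute deviation, over all bank trials, between the unit's
#' response and the trial's disparity magnitude (the trained code is
#' degrees of disparity within the genome's polarity channel; near and
#' rel_near channels code the magnitude of their negative labels).
#'
#' @param genome a `genome`.
#' @param bank a `stimulus_bank` compatible with the genome's stage
#'   (absolute/control banks for second order, relative banks for third).
#' @param assembly the [place_monocular_pairs()] assembly.
#' @param second_order for third-order genomes: list with elements `far`
#'   and `near`, the frozen evolved second-order genomes cloned at the
#'   reference position.
#' @return Summed error in degrees (`>= 0`).
#' @export
lifetime_error <- function(genome, bank, assembly, second_order = NULL) {
  M <- .stage_inputs(genome$stage, bank, assembly, second_order)
  resp <- .sum_of_sigmoids(M, genome)
  sum(abs(resp - abs(bank$labels)))
}

# Input matrix (n x 4) for a stage given a bank.
.stage_inputs <- function(stage, bank, assembly, second_order = NULL) {
  act <- bank_activities(bank, assembly)
  if (stage == "second_order") {
    if (!bank$kind %in% c("absolute_far", "absolute_near", "control")) {
      stop(sprintf("bank kind '%s' incompatible with a second-order genome",
                   bank$kind))
    }
    cbind(act[, "fixation", "contralateral"], act[, "fixation", "ipsilateral"],
          act[, "target", "contralateral"], act[, "target", "ipsilateral"])
  } else {
    if (bank$kind != "relative") {
      stop("third-order genomes require a relative bank")
    }
    if (is.null(second_order) || !all(c("far", "near") %in% names(second_order))) {
      stop("third-order evaluation requires frozen second-order far and near genomes")
    }
    M_tgt <- cbind(act[, "fixation", "contralateral"],
                   act[, "fixation", "ipsilateral"],
                   act[, "target", "contralateral"],
                   act[, "target", "ipsilateral"])
    M_ref <- cbind(act[, "fixation", "contralateral"],
                   act[, "fixation", "ipsilateral"],
                   act[, "reference", "contralateral"],
                   act[, "reference", "ipsilateral"])
    cbind(
      second_order_response(M_tgt, second_order$far),
      second_order_response(M_tgt, second_order$near),
      second_order_response(M_ref, second_order$far),
      second_order_response(M_ref, second_order$near)
    ) / .DISPARITY_CEILING
  }
}

#' Selection weights from lifetime errors
#'
#' `score_k = max_j(error_j) - error_k`: lower error, larger roulette
#' sector. When all errors are equal every score is 1 (uniform fallback).
#'
#' @param errors non-negative lifetime errors.
#' @return Non-negative selection weights, same length.
#' @export
success_scores <- function(errors) {
  if (any(errors < 0)) stop("negative lifetime error")
  s <- max(errors) - errors
  if (all(s == 0)) rep(1, length(errors)) else s
}

#' Roulette-wheel parent selection
#'
#' Fitness-proportionate sampling: `n_draws` independent draws with
#' probability `score_k / sum(scores)`, implemented with cumulative sums
#' over half-open intervals (a draw landing exactly on a boundary goes to
#' the higher index's interval, and zero-width sectors are never hit).
#'
#' @param scores non-negative selection weights.
#' @param n_draws number of parents to draw.
#' @return Integer vector of parent indices.
#' @export
roulette_select <- function(scores, n_draws) {
  if (any(scores < 0)) stop("negative selection score")
  if (all(scores == 0)) {
    message("all selection scores zero; falling back to uniform selection")
    scores <- rep(1, length(scores))
  }
  breaks <- cumsum(scores / sum(scores))
  findInterval(runif(n_draws), breaks) + 1L
}

# Sequential parameter exchange on the 16 x n matrix: each individual, with
# probability p, is paired with another uniformly chosen individual and each
# scalar parameter is swapped between the two with probability 1/2. Every
# operation is a transposition, so the population-wide multiset of values in
# every parameter row is conserved exactly.
.exchange_matrix <- function(P, p) {
  n <- ncol(P)
  if (n < 2 || p <= 0) return(P)
  who <- which(runif(n) < p)
  if (!length(who)) return(P)
  # uniform partner other than self; all draws taken up front, swaps applied
  # sequentially in individual order
  js <- floor(runif(length(who)) * (n - 1)) + 1L
  js <- js + (js >= who)
  masks <- matrix(runif(16L * length(who)) < 0.5, nrow = 16L)
  for (i in seq_along(who)) {
    k <- who[i]; j <- js[i]; m <- masks[, i]
    tmp <- P[m, k]
    P[m, k] <- P[m, j]
    P[m, j] <- tmp
  }
  P
}

#' Exchange parameters across a population of genomes
#'
#' Each individual, with probability `p`, is paired with another uniformly
#' chosen individual, and each scalar parameter (A, B, C and sign of every
#' connection) is swapped between the two with probability 1/2. Swapping
#' conserves the multiset of parameter values across the population.
#'
#' @param population list of `genome` objects sharing stage and polarity.
#' @param p exchange probability per individual.
#' @return The exchanged population (same length, same stage/polarity).
#' @export
exchange_parameters <- function(population, p) {
  stopifnot(length(population) >= 1, p >= 0, p <= 1)
  if (length(population) == 1) {
    if (p > 0) message("population of size 1: exchange is a no-op")
    return(population)
  }
  P <- vapply(population, .genome_to_column, numeric(16))
  P <- .exchange_matrix(P, p)
  lapply(seq_len(ncol(P)), function(i)
    .column_to_genome(P[, i], population[[1]]$stage, population[[1]]$polarity))
}

# Gaussian mutation with bound clipping on continuous rows; sign rows flip
# with the same per-parameter probability.
.mutate_matrix <- function(P, prob, scale, bounds = .param_bounds()) {
  if (prob <= 0) return(P)
  n <- ncol(P)
  b <- bounds
  cont <- c(.P_A, .P_B, .P_C)
  m <- matrix(runif(12 * n) < prob, 12, n)
  if (any(m)) {
    sd_row <- scale * (b$hi - b$lo)
    step <- matrix(rnorm(12 * n), 12, n) * sd_row
    Pc <- P[cont, , drop = FALSE]
    Pc[m] <- Pc[m] + step[m]
    Pc <- pmin(pmax(Pc, b$lo), b$hi)
    P[cont, ] <- Pc
  }
  fl <- matrix(runif(4 * n) < prob, 4, n)
  P[.P_S, ][fl] <- -P[.P_S, ][fl]
  P
}

# Core generational loop for one population. input_fn(gen_seed) must return
# list(M = n x 4 input matrix, targets = disparity magnitudes).
.run_population <- function(cfg, input_fn, pop_seed, stage = "second_order") {
  set.seed(pop_seed)
  bounds <- .param_bounds(stage)
  P <- .init_population_matrix(cfg$population_size)
  trace_mean <- numeric(cfg$generations)
  trace_best <- numeric(cfg$generations)
  for (gen in seq_len(cfg$generations)) {
    inp <- input_fn(.split_seed(pop_seed, gen))
    R <- .population_responses(inp$M, P)
    err <- colSums(abs(R - inp$targets))
    trace_mean[gen] <- mean(err)
    trace_best[gen] <- min(err)
    idx <- roulette_select(success_scores(err), cfg$population_size)
    P <- P[, idx, drop = FALSE]
    P <- .exchange_matrix(P, cfg$exchange_probability)
    P <- .mutate_matrix(P, cfg$mutation_probability, cfg$mutation_scale, bounds)
  }
  # final standing of the evolved population on an evaluation lifetime
  inp <- input_fn(.split_seed(pop_seed, cfg$generations + 1L))
  err <- colSums(abs(.population_responses(inp$M, P) - inp$targets))
  list(P = P, final_errors = err, trace_mean = trace_mean,
       trace_best = trace_best)
}

.new_run <- function(stage, polarity, cfg, pops, pop_seeds, assembly,
                     bank_params, second_order = NULL) {
  r <- list(
    stage = stage, polarity = polarity, config = cfg,
    traces = vapply(pops, `[[`, numeric(cfg$generations), "trace_mean"),
    best_traces = vapply(pops, `[[`, numeric(cfg$generations), "trace_best"),
    populations = lapply(pops, `[[`, "P"),
    final_errors = lapply(pops, `[[`, "final_errors"),
    pop_seeds = pop_seeds,
    assembly = assembly,
    bank_params = bank_params,
    second_order = second_order
  )
  class(r) <- "evo_run"
  r
}

#' @export
print.evo_run <- function(x, ...) {
  final <- vapply(seq_len(x$config$n_populations), function(p)
    min(x$final_errors[[p]]) / x$config$lifetime_stimuli, numeric(1))
  cat(sprintf(
    "<evo_run> %s / %s: %d populations, %d generations; final best MAE %.4f-%.4f deg\n",
    x$stage, x$polarity, x$config$n_populations, x$config$generations,
    min(final), max(final)))
  invisible(x)
}

#' Evolve second-order absolute-disparity units
#'
#' Runs the full genetic algorithm for each replicate population: a fresh
#' seeded 200-stimulus bank per generation, lifetime-error evaluation of
#' every network (monocular activities computed once per bank and shared),
#' roulette selection, parameter exchange, and Gaussian mutation. There is
#' no elitism. Networks of one run code a single polarity (far or near);
#' with `bank_kind = "control"` the target position is randomized per
#' stimulus (retinotopy control).
#'
#' @param config an [evolution_config()].
#' @param polarity `"far"` or `"near"`.
#' @param bank_kind `"absolute"` (fixed retinotopy) or `"control"`
#'   (position-randomized).
#' @param assembly optional pre-built absolute-stage assembly.
#' @return An object of class `evo_run`: per-generation mean and best
#'   lifetime-error traces per population, final populations, evaluation
#'   errors, and the seeds needed for bit-identical reproduction.
#' @export
evolve_absolute <- function(config, polarity = c("far", "near"),
                            bank_kind = c("absolute", "control"),
                            assembly = NULL) {
  polarity <- match.arg(polarity)
  bank_kind <- match.arg(bank_kind)
  if (is.null(assembly)) assembly <- place_monocular_pairs(stage = "absolute")
  make_bank <- if (bank_kind == "absolute") {
    function(seed) make_absolute_bank(config$lifetime_stimuli, polarity,
                                      config$max_disparity, seed = seed)
  } else {
    function(seed) make_control_bank(config$lifetime_stimuli,
                                     config$max_disparity, seed = seed,
                                     polarity = polarity,
                                     geometry = assembly$geometry)
  }
  input_fn <- function(seed) {
    bank <- make_bank(seed)
    list(M = .stage_inputs("second_order", bank, assembly),
         targets = abs(bank$labels))
  }
  pop_seeds <- vapply(seq_len(config$n_populations), function(p)
    .split_seed(config$master_seed, p * 1000003L), integer(1))
  pops <- lapply(pop_seeds, function(s)
    .run_population(config, input_fn, s, "second_order"))
  .new_run("second_order", polarity, config, pops, pop_seeds, assembly,
           bank_params = list(kind = bank_kind))
}

#' Evolve third-order relative-disparity units
#'
#' The frozen second-order far and near genomes (evolved separately and
#' beforehand) are cloned at the reference position; only the third-order
#' connection parameters evolve, against relative-disparity labels from
#' banks containing all three surface configurations (both-far, straddle,
#' both-near).
#'
#' @param config an [evolution_config()].
#' @param polarity `"rel_far"` or `"rel_near"`.
#' @param second_order list with elements `far` and `near`: the frozen
#'   evolved second-order genomes.
#' @param assembly optional pre-built relative-stage assembly.
#' @return An `evo_run` (stage `third_order`).
#' @export
evolve_relative <- function(config, polarity = c("rel_far", "rel_near"),
                            second_order, assembly = NULL) {
  polarity <- match.arg(polarity)
  if (missing(second_order) || is.null(second_order) ||
      !all(c("far", "near") %in% names(second_order))) {
    stop("evolve_relative requires frozen second-order far and near genomes")
  }
  if (is.null(assembly)) assembly <- place_monocular_pairs(stage = "relative")
  input_fn <- function(seed) {
    bank <- make_relative_bank(config$lifetime_stimuli, config$max_disparity,
                               polarity, seed = seed)
    list(M = .stage_inputs("third_order", bank, assembly, second_order),
         targets = abs(bank$labels))
  }
  pop_seeds <- vapply(seq_len(config$n_populations), function(p)
    .split_seed(config$master_seed, p * 1000003L), integer(1))
  pops <- lapply(pop_seeds, function(s)
    .run_population(config, input_fn, s, "third_order"))
  .new_run("third_order", polarity, config, pops, pop_seeds, assembly,
           bank_params = list(kind = "relative"), second_order = second_order)
}

#' Best evolved genomes of a run
#'
#' @param run an `evo_run`.
#' @param k genomes per population (by final evaluation error, ascending).
#' @return If `k = 1`, a list with one `genome` per population; otherwise a
#'   list of lists.
#' @export
best_genomes <- function(run, k = 1) {
  out <- lapply(seq_along(run$populations), function(p) {
    ord <- order(run$final_errors[[p]])[seq_len(k)]
    gs <- lapply(ord, function(i)
      .column_to_genome(run$populations[[p]][, i], run$stage, run$polarity))
    if (k == 1) gs[[1]] else gs
  })
  out
}

#' Held-out mean absolute error of a run's best genomes
#'
#' Evaluates each population's best evolved genome on a fresh bank drawn
#' with an independent seed, optionally restricted to trials whose
#' disparity magnitude lies within `within` (e.g. the evolved disparity
#' limit).
#'
#' @param run an `evo_run`.
#' @param n held-out trials.
#' @param seed bank seed (independent of training seeds).
#' @param within optional magnitude cutoff in degrees.
#' @return Numeric vector: per-population mean absolute error, degrees.
#' @export
held_out_mae <- function(run, n = 500, seed = 99991L, within = NULL) {
  cfg <- run$config
  bank <- switch(
    run$bank_params$kind,
    absolute = make_absolute_bank(n, run$polarity, cfg$max_disparity, seed = seed),
    control = make_control_bank(n, cfg$max_disparity, seed = seed,
                                polarity = run$polarity,
                                geometry = run$assembly$geometry),
    relative = make_relative_bank(n, cfg$max_disparity, run$polarity, seed = seed)
  )
  M <- .stage_inputs(run$stage, bank, run$assembly, run$second_order)
  keep <- if (is.null(within)) rep(TRUE, n) else abs(bank$labels) <= within
  vapply(best_genomes(run), function(g) {
    resp <- .sum_of_sigmoids(M, g)
    mean(abs(resp - abs(bank$labels))[keep])
  }, numeric(1))
}
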