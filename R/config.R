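#' Default run configuration
#'
#' The full set of model constants in one nested list: sensor geometry,
#' scene defaults, the preset monocular front-end parameters (including the
#' output sigmoid A 0.9771, B 5.7152, C 1.7300), the evolution regime, and
#' the probe grids and tolerances. Every field has a documented default;
#' [load_config()] validates user files against this tree.
#'
#' @return Nested named list of class `run_config`.
#' @export
default_config <- function() {
  cfg <- list(
    geometry = list(width_px = 200L, height_px = 40L, pixel_deg = 0.01),
    scene = list(
      target_offset = -0.3, reference_offset = -0.6,
      fixation_offset = 0, fixation_width = 0.3, strip_width = 0.15,
      figure_luminance = 400, background_luminance = 1,
      max_disparity = 0.18
    ),
    frontend = list(
      output_A = 0.9771, output_B = 5.7152, output_C = 1.7300,
      center_A = 1, surround_A = 0.125, subregion_B = 6, subregion_C = 1.5
    ),
    evolution = list(
      n_populations = 20L, population_size = 500L,
      lifetime_stimuli = 200L, generations = 2500L,
      exchange_probability = 0.8, mutation_probability = 0.02,
      mutation_scale = 0.05
    ),
    probes = list(
      grid_step = 0.01, limit_tolerance = 0.02, od_sweep_max = 0.09
    ),
    master_seed = 1L
  )
  class(cfg) <- "run_config"
  cfg
}

# Recursive strict merge of user values into the default tree; unknown keys
# and type mismatches are rejected with the offending key's full path.
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop(sprintf("config key '%s' must be a section", path))
  nm <- names(user)
  if (length(user) && (is.null(nm) || any(nm == ""))) {
    stop(sprintf("unnamed entry in config section '%s'", path))
  }
  for (k in nm) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(defaults)) {
      stop(sprintf("unknown config key '%s'", full))
    }
    if (is.list(defaults[[k]])) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]], full)
    } else {
      v <- user[[k]]
      if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
        stop(sprintf("config key '%s' must be a single finite number", full))
      }
      defaults[[k]] <- if (is.integer(defaults[[k]])) as.integer(v) else as.numeric(v)
    }
  }
  defaults
}

.validate_config <- function(cfg) {
  g <- cfg$geometry
  sensor_geometry(g$width_px, g$height_px, g$pixel_deg)   # range checks
  s <- cfg$scene
  if (s$figure_luminance <= s$background_luminance) {
    stop("config key 'scene.figure_luminance' must exceed the background")
  }
  if (s$max_disparity <= 0 || s$max_disparity > 0.18) {
    stop("config key 'scene.max_disparity' out of range (0, 0.18]")
  }
  e <- cfg$evolution
  evolution_config(
    n_populations = e$n_populations, population_size = e$population_size,
    lifetime_stimuli = e$lifetime_stimuli, generations = e$generations,
    exchange_probability = e$exchange_probability,
    mutation_probability = e$mutation_probability,
    mutation_scale = e$mutation_scale,
    max_disparity = s$max_disparity, master_seed = cfg$master_seed
  )
  invisible(cfg)
}

#' Load a run configuration from a JSON file
#'
#' Omitted fields take their documented defaults; unknown keys, unnamed
#' entries, type mismatches and out-of-range values are rejected with a
#' message naming the key. An empty file (or empty JSON object) yields the
#' full default configuration.
#'
#' @param path JSON file.
#' @return A validated `run_config`.
#' @seealso [default_config()], [save_config()]
#' @export
load_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (!nzchar(trimws(txt))) list() else
    jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  cfg <- .merge_config(default_config(), user)
  class(cfg) <- "run_config"
  .validate_config(cfg)
  cfg
}

#' Save a run configuration as JSON
#' @param config a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Build the model objects described by a configuration
#'
#' @param config a `run_config`.
#' @param stage `"absolute"` or `"relative"`.
#' @return List with `geometry`, `assembly` and `evolution` (an
#'   [evolution_config()]).
#' @export
config_objects <- function(config, stage = c("absolute", "relative")) {
  stage <- match.arg(stage)
  g <- config$geometry
  f <- config$frontend
  geometry <- sensor_geometry(g$width_px, g$height_px, g$pixel_deg)
  assembly <- place_monocular_pairs(
    geometry, stage,
    subregion_params = default_subregion_params(
      center_A = f$center_A, surround_A = f$surround_A,
      B = f$subregion_B, C = f$subregion_C),
    output_params = sigmoid_params(f$output_A, f$output_B, f$output_C, 1)
  )
  e <- config$evolution
  evo <- evolution_config(
    n_populations = e$n_populations, population_size = e$population_size,
    lifetime_stimuli = e$lifetime_stimuli, generations = e$generations,
    exchange_probability = e$exchange_probability,
    mutation_probability = e$mutation_probability,
    mutation_scale = e$mutation_scale,
    max_disparity = config$scene$max_disparity,
    master_seed = config$master_seed
  )
  list(geometry = geometry, assembly = assembly, evolution = evo)
}

#' Deterministic fixture suite
#'
#' Builds the small, fully seeded objects the unit tests (and any quick
#' interactive exploration) rely on: a 12-stimulus absolute bank per
#' polarity, a relative bank covering all three surface configurations, an
#' anti-correlated pair, and hand-constructed genomes with known probe
#' outcomes: a `perfect` responder (constant output equal to its
#' constant-disparity bank's label, lifetime error 0), a `one_eyed` genome
#' (zero gain on the ipsilateral lines, ODI +1), a `mirror` genome
#' (identical contralateral and ipsilateral connections, ODI 0), and a
#' `zero_gain` genome (all gains 0, degenerate probes).
#'
#' @param seed integer seed.
#' @param dir optional directory; when given, banks (manifest + scenes) and
#'   genomes (JSON) are written there.
#' @return Named list of fixtures.
#' @export
generate_fixtures <- function(seed = 1L, dir = NULL) {
  abs_far <- make_absolute_bank(12, "far", seed = .split_seed(seed, 1))
  abs_near <- make_absolute_bank(12, "near", seed = .split_seed(seed, 2))
  relative <- make_relative_bank(60, polarity = "rel_far",
                                 seed = .split_seed(seed, 3))
  pair <- render_stereo(scene_spec(target_disparity = 0.04))
  anticorr <- anticorrelate(pair, "contralateral")

  const_d <- 0.1
  constant_bank <- .new_bank(
    kind = "absolute_far",
    scenes = data.frame(target_offset = rep(-0.3, 12),
                        target_disparity = rep(const_d, 12)),
    labels = rep(const_d, 12), seed = seed,
    params = list(polarity = "far", max_disparity = 0.18,
                  target_offset = -0.3, strip_width = 0.15)
  )
  # B = 0, C = 0: the sigmoid is the constant A/2 regardless of input
  perfect <- new_genome("second_order", "far", list(
    sigmoid_params(2 * const_d, 0, 0, 1), sigmoid_params(0, 0, 0, 1),
    sigmoid_params(0, 0, 0, 1), sigmoid_params(0, 0, 0, 1)
  ))
  active <- sigmoid_params(0.3, 6, 2, 1)
  off <- sigmoid_params(0, 0, 0, 1)
  one_eyed <- new_genome("second_order", "far",
                         list(active, off, active, off))
  mirror <- new_genome("second_order", "far",
                       list(active, active, active, active))
  zero_gain <- new_genome("second_order", "far", list(off, off, off, off))

  fx <- list(
    abs_far_bank = abs_far, abs_near_bank = abs_near,
    relative_bank = relative, anticorr_pair = anticorr,
    constant_bank = constant_bank,
    genomes = list(perfect = perfect, one_eyed = one_eyed,
                   mirror = mirror, zero_gain = zero_gain),
    seed = seed
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_bank(abs_far, file.path(dir, "abs_far"))
    write_bank(abs_near, file.path(dir, "abs_near"))
    write_bank(relative, file.path(dir, "relative"))
    write_bank(constant_bank, file.path(dir, "constant"))
    write_genomes(fx$genomes, file.path(dir, "genomes.json"),
                  provenance = list(fixture_seed = seed))
  }
  fx
}
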