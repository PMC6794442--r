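# Measurements on evolved networks: disparity tuning curves (conventional
# and anti-correlated), ocular dominance, connection classification, the
# operational disparity limit, dominance-tuning correlation, and the
# retinotopy control verdict.

# Input row (1 x 4) for a genome on a single rendered pair.
.pair_inputs <- function(stage, pair, assembly, second_order = NULL) {
  act <- pair_activities(pair, assembly)
  M_tgt <- c(act["fixation", "contralateral"], act["fixation", "ipsilateral"],
             act["target", "contralateral"], act["target", "ipsilateral"])
  if (stage == "second_order") return(matrix(M_tgt, 1))
  M_ref <- c(act["fixation", "contralateral"], act["fixation", "ipsilateral"],
             act["reference", "contralateral"], act["reference", "ipsilateral"])
  matrix(c(
    second_order_response(matrix(M_tgt, 1), second_order$far),
    second_order_response(matrix(M_tgt, 1), second_order$near),
    second_order_response(matrix(M_ref, 1), second_order$far),
    second_order_response(matrix(M_ref, 1), second_order$near)
  ), 1) / .DISPARITY_CEILING
}

# Scene for a probe disparity. Second order: the target strip carries the
# disparity. Third order: the target strip carries the relative disparity on
# top of `reference_disparity`.
.probe_scene <- function(stage, d, reference_disparity = 0) {
  if (stage == "second_order") {
    scene_spec(target_disparity = d)
  } else {
    scene_spec(target_disparity = d + reference_disparity,
               reference_disparity = reference_disparity)
  }
}

# n_disp x 4 input matrix for a probe sweep shared by a set of genomes.
.sweep_inputs <- function(stage, disparities, assembly, second_order = NULL,
                          mode = "conventional",
                          anticorrelated_eye = "contralateral",
                          reference_disparity = 0) {
  t(vapply(disparities, function(d) {
    pair <- render_stereo(.probe_scene(stage, d, reference_disparity),
                          assembly$geometry)
    if (mode == "anticorrelated") pair <- anticorrelate(pair, anticorrelated_eye)
    .pair_inputs(stage, pair, assembly, second_order)[1, ]
  }, numeric(4)))
}

#' Disparity tuning curve of evolved binocular units
#'
#' For each probe disparity the stimulus is rendered (contrast-inverting
#' one eye when `mode = "anticorrelated"`), the forward pass is run for
#' every genome, and the mean and standard deviation across genomes
#' (typically one best genome per replicate population) are aggregated.
#'
#' Second-order genomes are probed over absolute target disparity;
#' third-order genomes over relative disparity, obtained by sweeping the
#' target against a fixed `reference_disparity`.
#'
#' @param genomes list of `genome` objects sharing stage and polarity.
#' @param assembly the matching [place_monocular_pairs()] assembly.
#' @param disparities probe grid, degrees, strictly increasing. The
#'   anti-correlated default uses 0.02-degree steps so every displaced edge
#'   falls on a whole pixel and the images stay binary.
#' @param mode `"conventional"` or `"anticorrelated"`.
#' @param second_order frozen second-order genomes (third-order probes).
#' @param anticorrelated_eye which eye is contrast-inverted.
#' @param reference_disparity reference-strip disparity for third-order
#'   probes, degrees.
#' @return An object of class `tuning_curve`: `disparities`, per-disparity
#'   `mean` and `sd` across genomes, the full `responses` matrix
#'   (disparities x genomes), and mode/stage/polarity tags.
#' @export
tuning_curve <- function(genomes, assembly,
                         disparities = NULL,
                         mode = c("conventional", "anticorrelated"),
                         second_order = NULL,
                         anticorrelated_eye = c("contralateral", "ipsilateral"),
                         reference_disparity = 0) {
  mode <- match.arg(mode)
  anticorrelated_eye <- match.arg(anticorrelated_eye)
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  stage <- genomes[[1]]$stage
  if (is.null(disparities)) {
    disparities <- if (mode == "conventional") seq(-0.18, 0.18, by = 0.01)
    else seq(-0.18, 0.18, by = 0.02)
  }
  if (any(diff(disparities) <= 0)) stop("disparities must be strictly increasing")
  M <- .sweep_inputs(stage, disparities, assembly, second_order, mode,
                     anticorrelated_eye, reference_disparity)
  responses <- vapply(genomes, function(g) .sum_of_sigmoids(M, g),
                      numeric(length(disparities)))
  responses <- matrix(responses, nrow = length(disparities))
  tc <- list(
    disparities = disparities,
    mean = rowMeans(responses),
    sd = apply(responses, 1, stats::sd),
    responses = responses,
    mode = mode, stage = stage, polarity = genomes[[1]]$polarity,
    reference_disparity = reference_disparity
  )
  class(tc) <- "tuning_curve"
  tc
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf(
    "<tuning_curve> %s / %s, %s: %d disparities in [%+0.2f, %+0.2f], %d genomes\n",
    x$stage, x$polarity, x$mode, length(x$disparities),
    min(x$disparities), max(x$disparities), ncol(x$responses)))
  invisible(x)
}

# Render the probed eye's monocular image: the full scene, with the
# depth-bearing strips translated by `shift` degrees, in one eye; uniform
# background in the other. Achieved by rendering a stereo scene whose
# disparity displaces the probed eye by `shift` and then blanking the
# other eye.
.monocular_pair <- function(eye, shift, assembly) {
  d <- if (eye == "contralateral") -2 * shift else 2 * shift
  has_ref <- assembly$stage == "relative"
  sc <- scene_spec(target_disparity = d,
                   reference_disparity = if (has_ref) d else NA_real_)
  pair <- render_stereo(sc, assembly$geometry)
  other <- if (eye == "contralateral") "right" else "left"
  pair[[other]][] <- pair$background_luminance
  pair
}

#' Ocular dominance index of a binocular unit
#'
#' Probes each eye alone: the scene is presented to one eye (its
#' depth-bearing strips swept over `sweep` displacements) while the other
#' eye sees uniform background, and the eye's modulation `M` is the
#' peak-to-trough range of the unit's response over the sweep. The index is
#' `ODI = (M_contra - M_ipsi) / (M_contra + M_ipsi)`, +1 for a fully
#' contralateral unit, bounded in `[-1, 1]`. Response-based (not
#' weight-based) because the evolved sigmoid nonlinearity makes raw gains
#' incomparable across connections.
#'
#' @param genome an evolved `genome` (second or third order).
#' @param assembly the matching assembly.
#' @param second_order frozen second-order genomes (third order only).
#' @param sweep monocular edge displacements, degrees.
#' @param preferred_depth also record the disparity of maximal response on
#'   the conventional tuning curve.
#' @return An object of class `dominance_record`: `odi`, per-eye
#'   modulations `M_contra` and `M_ipsi`, `degenerate` flag (both
#'   modulations zero; `odi` reported 0), `preferred_depth`, and tags.
#' @export
ocular_dominance_index <- function(genome, assembly, second_order = NULL,
                                   sweep = seq(-0.09, 0.09, by = 0.01),
                                   preferred_depth = TRUE) {
  dominance_records(list(genome), assembly, second_order, sweep,
                    preferred_depth)[[1]]
}

# Input matrices for a monocular probe sweep of one eye.
.monocular_sweep_inputs <- function(stage, eye, sweep, assembly,
                                    second_order = NULL) {
  t(vapply(sweep, function(s) {
    .pair_inputs(stage, .monocular_pair(eye, s, assembly), assembly,
                 second_order)[1, ]
  }, numeric(4)))
}

#' Ocular dominance records for a set of genomes
#'
#' Batch form of [ocular_dominance_index()]: the monocular probe sweeps and
#' the conventional tuning curve are rendered once and shared across all
#' genomes (which must share stage and polarity).
#'
#' @inheritParams ocular_dominance_index
#' @param genomes list of `genome` objects.
#' @return List of `dominance_record`s.
#' @export
dominance_records <- function(genomes, assembly, second_order = NULL,
                              sweep = seq(-0.09, 0.09, by = 0.01),
                              preferred_depth = TRUE) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  stage <- genomes[[1]]$stage
  Mc <- .monocular_sweep_inputs(stage, "contralateral", sweep, assembly,
                                second_order)
  Mi <- .monocular_sweep_inputs(stage, "ipsilateral", sweep, assembly,
                                second_order)
  pd <- rep(NA_real_, length(genomes))
  if (preferred_depth) {
    tc <- tuning_curve(genomes, assembly, second_order = second_order)
    pd <- tc$disparities[apply(tc$responses, 2, which.max)]
  }
  lapply(seq_along(genomes), function(j) {
    g <- genomes[[j]]
    rc <- .sum_of_sigmoids(Mc, g)
    ri <- .sum_of_sigmoids(Mi, g)
    mods <- c(max(rc) - min(rc), max(ri) - min(ri))
    degenerate <- sum(mods) == 0
    rec <- list(
      odi = if (degenerate) 0 else (mods[1] - mods[2]) / sum(mods),
      M_contra = mods[1], M_ipsi = mods[2], degenerate = degenerate,
      preferred_depth = pd[j], stage = g$stage, polarity = g$polarity
    )
    class(rec) <- "dominance_record"
    rec
  })
}

#' @export
print.dominance_record <- function(x, ...) {
  cat(sprintf("<dominance_record> %s / %s: ODI %+0.3f (Mc %.4f, Mi %.4f)%s\n",
              x$stage, x$polarity, x$odi, x$M_contra, x$M_ipsi,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Classify a genome's connections as excitatory, inhibitory or negligible
#'
#' Each connection's contribution over the conventional probe sweep is
#' `sign * A * logistic(input)`; its swing is the peak-to-trough range.
#' Connections whose swing is below `threshold` times the unit's total
#' response range are negligible ("little or no effect"); otherwise the
#' connection sign labels it excitatory or inhibitory.
#'
#' @param genome a `genome`.
#' @param assembly the matching assembly.
#' @param threshold negligibility threshold as a fraction of the total
#'   response range.
#' @param disparities probe grid.
#' @param second_order frozen second-order genomes (third order only).
#' @return Named character vector over the genome's input lines, with the
#'   per-connection swings as attribute `swing`.
#' @export
classify_connections <- function(genome, assembly, threshold = 0.01,
                                 disparities = seq(-0.18, 0.18, by = 0.01),
                                 second_order = NULL) {
  stopifnot(threshold >= 0)
  M <- .sweep_inputs(genome$stage, disparities, assembly, second_order)
  contrib <- vapply(1:4, function(c) logistic(M[, c], genome$connections[[c]]),
                    numeric(nrow(M)))
  swings <- apply(contrib, 2, function(x) max(x) - min(x))
  total <- {
    r <- rowSums(contrib)
    max(r) - min(r)
  }
  labels <- vapply(1:4, function(c) {
    if (genome$connections[[c]]$A == 0 || total == 0 ||
        swings[c] < threshold * total) "negligible"
    else if (genome$connections[[c]]$sign > 0) "excitatory"
    else "inhibitory"
  }, character(1))
  names(labels) <- genome$input_labels
  attr(labels, "swing") <- stats::setNames(swings, genome$input_labels)
  labels
}

#' Operational disparity limit of evolved units
#'
#' The largest probed disparity magnitude at which the units still encode
#' disparity to within `tolerance`: per population the absolute response
#' error `|response - |d||` is taken on the polarity-matching side of its
#' conventional tuning curve, the median across populations (pooled over
#' the supplied curves) is formed at each probed magnitude, and the limit
#' is the largest magnitude whose median error is `<= tolerance`. If no
#' magnitude qualifies the limit is 0 and the result carries attribute
#' `met = FALSE`.
#'
#' @param curves a conventional `tuning_curve` or list of them (e.g. far
#'   and near), each holding one response column per population.
#' @param tolerance allowed median coding error, degrees.
#' @return Limit in degrees, with attribute `met`.
#' @export
disparity_limit <- function(curves, tolerance = 0.02) {
  if (inherits(curves, "tuning_curve")) curves <- list(curves)
  err_series <- list()
  for (tc in curves) {
    side <- if (tc$polarity %in% c("far", "rel_far")) tc$disparities > 0
            else tc$disparities < 0
    mags <- abs(tc$disparities[side])
    E <- abs(tc$responses[side, , drop = FALSE] - mags)
    o <- order(mags)
    for (j in seq_len(ncol(E))) {
      err_series[[length(err_series) + 1]] <-
        list(mag = mags[o], err = E[o, j])
    }
  }
  mags <- err_series[[1]]$mag
  same <- vapply(err_series, function(s)
    length(s$mag) == length(mags) && all(abs(s$mag - mags) < 1e-9), logical(1))
  if (!all(same)) stop("curves must share one probe-magnitude grid")
  med <- vapply(seq_along(mags), function(i)
    stats::median(vapply(err_series, function(s) s$err[i], numeric(1))),
    numeric(1))
  ok <- med <= tolerance
  if (!any(ok)) {
    return(structure(0, met = FALSE))
  }
  structure(max(mags[ok]), met = TRUE)
}

#' Correlation between depth tuning and ocular dominance
#'
#' Pearson correlation (two-sided p) between each unit's preferred depth
#' and its ocular dominance index. Constant input in either variable gives
#' `r = 0` with a degenerate flag.
#'
#' @param records list of `dominance_record`s with preferred depths, or a
#'   data frame with columns `odi` and `preferred_depth`.
#' @return List with `r`, `p`, `n` and `degenerate`.
#' @export
dominance_tuning_correlation <- function(records) {
  df <- if (is.data.frame(records)) records else
    data.frame(
      odi = vapply(records, `[[`, numeric(1), "odi"),
      preferred_depth = vapply(records, `[[`, numeric(1), "preferred_depth")
    )
  if (nrow(df) < 3) stop("need at least 3 units")
  if (stats::sd(df$odi) == 0 || stats::sd(df$preferred_depth) == 0) {
    return(list(r = 0, p = NA_real_, n = nrow(df), degenerate = TRUE))
  }
  ct <- stats::cor.test(df$odi, df$preferred_depth, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(df),
       degenerate = FALSE)
}

# Mean absolute error a label-independent constant responder attains on a
# run's stimulus distribution: the optimal constant is the median of the
# disparity magnitudes.
.constant_baseline_mae <- function(run, n = 2000) {
  cfg <- run$config
  seed <- .split_seed(cfg$master_seed, 777777L)
  bank <- switch(
    run$bank_params$kind,
    absolute = make_absolute_bank(n, run$polarity, cfg$max_disparity, seed = seed),
    control = make_control_bank(n, cfg$max_disparity, seed = seed,
                                polarity = run$polarity,
                                geometry = run$assembly$geometry),
    relative = make_relative_bank(n, cfg$max_disparity, run$polarity, seed = seed)
  )
  mags <- abs(bank$labels)
  mean(abs(mags - stats::median(mags)))
}

# Median-across-populations mean per-trial error over the trailing
# generations of a run.
.final_median_mae <- function(run, window = 10) {
  gens <- nrow(run$traces)
  w <- max(1, gens - window + 1):gens
  stats::median(colMeans(run$traces[w, , drop = FALSE])) /
    run$config$lifetime_stimuli
}

#' Retinotopy control verdict
#'
#' Compares a position-randomized (control) evolution run with a
#' fixed-retinotopy run. A run's verdict is `"evolved"` if its final median
#' per-trial error (median across populations of the last-generations mean)
#' beats 0.8 times the constant-predictor baseline error on its own
#' stimulus distribution, and `"failed"` otherwise. Depth responses that
#' must be tied to fixed retinotopic locations show up as a failed control
#' next to an evolved fixed-position run.
#'
#' @param control_run `evo_run` trained on position-randomized banks.
#' @param retinotopic_run `evo_run` trained on fixed-position banks.
#' @param window trailing generations averaged for the final error.
#' @return List with `control_verdict`, `retinotopic_verdict`, per-run
#'   final errors and baselines, and both error traces.
#' @export
retinotopy_control_report <- function(control_run, retinotopic_run,
                                      window = 10) {
  comparable <- control_run$stage == retinotopic_run$stage &&
    control_run$config$lifetime_stimuli == retinotopic_run$config$lifetime_stimuli &&
    control_run$config$max_disparity == retinotopic_run$config$max_disparity
  if (!comparable) stop("runs are not comparable (stage or stimulus regime differ)")
  verdict_of <- function(run) {
    final <- .final_median_mae(run, window)
    base <- .constant_baseline_mae(run)
    list(verdict = if (final < 0.8 * base) "evolved" else "failed",
         final_error = final, baseline = base)
  }
  ctl <- verdict_of(control_run)
  ret <- verdict_of(retinotopic_run)
  list(
    control_verdict = ctl$verdict,
    retinotopic_verdict = ret$verdict,
    control = ctl, retinotopic = ret,
    control_trace = control_run$traces / control_run$config$lifetime_stimuli,
    retinotopic_trace = retinotopic_run$traces / retinotopic_run$config$lifetime_stimuli
  )
}
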