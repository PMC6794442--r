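# Evolvable binocular units. A second-order unit sums four sigmoid-
# transformed monocular inputs; a third-order unit sums four sigmoid-
# transformed second-order inputs. The genome of a unit is the ordered set
# of its four connection parameter sets (A, B, C, sign).

.SECOND_ORDER_INPUTS <- c("contra_fixation", "ipsi_fixation",
                          "contra_target", "ipsi_target")
.THIRD_ORDER_INPUTS <- c("far_target", "near_target",
                         "far_reference", "near_reference")

.ABS_POLARITIES <- c("far", "near")
.REL_POLARITIES <- c("rel_far", "rel_near")

# Disparity ceiling of the environment (degrees): half the 0.36 degree
# monocular receptive-field width. Second-order responses (a disparity code
# in degrees) are divided by this ceiling before driving third-order
# sigmoids, so every evolvable stage receives drives of order unity, just
# as subregion luminances are normalized by the figure luminance.
.DISPARITY_CEILING <- 0.18

#' Input-line labels of a genome's stage
#' @param stage `"second_order"` or `"third_order"`.
#' @return Character vector of 4 fixed input labels, in connection order.
#' @export
genome_input_labels <- function(stage = c("second_order", "third_order")) {
  stage <- match.arg(stage)
  if (stage == "second_order") .SECOND_ORDER_INPUTS else .THIRD_ORDER_INPUTS
}

#' Construct a binocular-unit genome
#'
#' @param stage `"second_order"` (inputs: contralateral and ipsilateral
#'   monocular units at fixation and target) or `"third_order"` (inputs:
#'   far- and near-tuned second-order units at target and reference). The
#'   input-line ordering is part of the contract so connection
#'   classification is unambiguous.
#' @param polarity the disparity channel the unit codes: `"far"`/`"near"`
#'   for second order, `"rel_far"`/`"rel_near"` for third order.
#' @param connections list of 4 [sigmoid_params()], one per input line.
#' @return An object of class `genome`.
#' @export
new_genome <- function(stage = c("second_order", "third_order"),
                       polarity, connections) {
  stage <- match.arg(stage)
  ok <- if (stage == "second_order") .ABS_POLARITIES else .REL_POLARITIES
  if (!polarity %in% ok) {
    stop(sprintf("polarity '%s' invalid for stage '%s'", polarity, stage))
  }
  stopifnot(length(connections) == 4,
            all(vapply(connections, inherits, logical(1), "sigmoid_params")))
  g <- list(stage = stage, polarity = polarity, connections = connections,
            input_labels = genome_input_labels(stage))
  class(g) <- "genome"
  g
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s / %s\n", x$stage, x$polarity))
  for (i in seq_along(x$connections)) {
    p <- x$connections[[i]]
    cat(sprintf("  %-16s %s A=%.4f B=%.4f C=%.4f\n", x$input_labels[i],
                if (p$sign > 0) "+" else "-", p$A, p$B, p$C))
  }
  invisible(x)
}

#' Random weak initial genome
#'
#' Networks start with weak but fully connected feedforward connections:
#' gains `A ~ U(0, 0.1)`, slopes `B ~ U(0, 10)`, offsets `C ~ U(-5, 5)` and
#' equiprobable connection signs. Draws come from the ambient R random
#' stream, so results are deterministic after `set.seed()`.
#'
#' @inheritParams new_genome
#' @return A `genome`.
#' @export
init_genome <- function(stage = c("second_order", "third_order"), polarity) {
  stage <- match.arg(stage)
  A <- runif(4, 0, 0.1); B <- runif(4, 0, 10); C <- runif(4, -5, 5)
  s <- sample(c(-1, 1), 4, replace = TRUE)
  new_genome(stage, polarity,
             lapply(1:4, function(i) sigmoid_params(A[i], B[i], C[i], s[i])))
}

# Shared sum-of-sigmoids forward pass. inputs: length-4 vector or n x 4
# matrix; returns scalar or length-n vector.
.sum_of_sigmoids <- function(inputs, genome) {
  if (is.matrix(inputs)) {
    if (ncol(inputs) != 4) stop("expected 4 input columns")
    val <- 0
    for (c in 1:4) val <- val + logistic(inputs[, c], genome$connections[[c]])
    val
  } else {
    if (length(inputs) != 4) stop("expected 4 inputs")
    sum(vapply(1:4, function(c) logistic(inputs[c], genome$connections[[c]]),
               numeric(1)))
  }
}

#' Second-order (absolute-disparity) unit response
#'
#' The unit's activity is the sum over its four connections of the sigmoid
#' transform of each monocular input, in the fixed order (contralateral at
#' fixation, ipsilateral at fixation, contralateral at target, ipsilateral
#' at target). The trained value is read as degrees of absolute disparity
#' within the genome's polarity channel.
#'
#' @param mono length-4 vector of monocular activities (or an `n x 4`
#'   matrix for many stimuli), in input-line order.
#' @param genome a second-order `genome`.
#' @return Scalar response (or length-`n` vector).
#' @export
second_order_response <- function(mono, genome) {
  stopifnot(inherits(genome, "genome"))
  if (genome$stage != "second_order") stop("genome stage must be second_order")
  .sum_of_sigmoids(mono, genome)
}

#' Third-order (relative-disparity) unit response
#'
#' Same sum-of-sigmoids contract as [second_order_response()], with inputs
#' in the fixed order (far at target, near at target, far at reference,
#' near at reference) taken from the frozen second-order units.
#'
#' Second-order responses are a disparity code in degrees; they are divided
#' by the 0.18 degree disparity ceiling of the environment before entering
#' the connection sigmoids, so third-order connections operate on the same
#' order-unity drive scale as every other stage.
#'
#' @param second length-4 vector (or `n x 4` matrix) of raw second-order
#'   responses in input-line order.
#' @param genome a third-order `genome`.
#' @return Scalar response (or length-`n` vector).
#' @export
third_order_response <- function(second, genome) {
  stopifnot(inherits(genome, "genome"))
  if (genome$stage != "third_order") stop("genome stage must be third_order")
  .sum_of_sigmoids(second / .DISPARITY_CEILING, genome)
}

# --- matrix population representation ---------------------------------------
# A population is a 16 x n matrix: rows 1-4 gains A, 5-8 slopes B, 9-12
# offsets C, 13-16 signs, one column per individual. This layout makes
# exchange, mutation and the vectorized forward pass cheap.

.P_A <- 1:4; .P_B <- 5:8; .P_C <- 9:12; .P_S <- 13:16

# Bounds for the continuous parameters during evolution (mutation clipping).
# A may grow past its weak-initialization range so evolved gains can span
# the trained response range; B stays non-negative (monotone transfer, the
# sign row carries inhibition); C keeps its initialization range.
# Both stages receive drives of order unity (luminance-normalized
# subregion means upstream of the monocular output; range-normalized
# disparity codes upstream of the third order), so one slope bound serves.
.param_bounds <- function(stage = "second_order") {
  list(lo = c(rep(0, 4), rep(0, 4), rep(-5, 4)),
       hi = c(rep(0.5, 4), rep(10, 4), rep(5, 4)))
}

.init_population_matrix <- function(n) {
  rbind(
    matrix(runif(4 * n, 0, 0.1), 4, n),
    matrix(runif(4 * n, 0, 10), 4, n),
    matrix(runif(4 * n, -5, 5), 4, n),
    matrix(sample(c(-1, 1), 4 * n, replace = TRUE), 4, n)
  )
}

.genome_to_column <- function(genome) {
  conn <- genome$connections
  c(vapply(conn, `[[`, numeric(1), "A"),
    vapply(conn, `[[`, numeric(1), "B"),
    vapply(conn, `[[`, numeric(1), "C"),
    vapply(conn, `[[`, numeric(1), "sign"))
}

.column_to_genome <- function(col, stage, polarity) {
  new_genome(stage, polarity, lapply(1:4, function(i) {
    sigmoid_params(col[.P_A[i]], col[.P_B[i]], col[.P_C[i]], col[.P_S[i]])
  }))
}

# Vectorized population forward pass. M: n_stim x 4 input matrix;
# P: 16 x n_ind parameter matrix. Returns n_stim x n_ind response matrix.
.population_responses <- function(M, P) {
  n_stim <- nrow(M)
  R <- matrix(0, n_stim, ncol(P))
  for (c in 1:4) {
    Z <- tcrossprod(M[, c], P[.P_B[c], ])
    R <- R + rep(P[.P_S[c], ] * P[.P_A[c], ], each = n_stim) /
      (1 + exp(rep(P[.P_C[c], ], each = n_stim) - Z))
  }
  R
}

#' Serialize genomes to JSON
#'
#' Writes one record per genome: stage, polarity, per-connection
#' `{A, B, C, sign}` in input-line order, plus any provenance fields
#' (run id, population, generation, seed).
#'
#' @param genomes a `genome` or list of genomes.
#' @param path output file.
#' @param provenance optional named list stored with every record.
#' @return `path`, invisibly.
#' @export
write_genomes <- function(genomes, path, provenance = NULL) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  recs <- lapply(seq_along(genomes), function(i) {
    g <- genomes[[i]]
    list(
      stage = g$stage, polarity = g$polarity,
      input_labels = g$input_labels,
      connections = lapply(g$connections, function(p)
        list(A = p$A, B = p$B, C = p$C, sign = p$sign)),
      provenance = provenance
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read genomes written by [write_genomes()]
#' @param path JSON file.
#' @return List of `genome` objects.
#' @export
read_genomes <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    new_genome(r$stage, r$polarity, lapply(r$connections, function(p)
      sigmoid_params(p$A, p$B, p$C, p$sign)))
  })
}
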