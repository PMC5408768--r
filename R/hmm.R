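#' Forward-backward over the kmer-state chain
#'
#' Log-space forward-backward with log-sum-exp accumulation over the
#' truncated sparse neighbour structure; the initial state distribution is
#' uniform over the `4^K` states. Besides per-event state posteriors the
#' pass accumulates the expected transition mass per shift class
#' (stay / step / one skip), which drives the Baum-Welch update of
#' `p_stay` / `p_skip`.
#'
#' @param events data.frame of events (`start`, `length`, `mean`, `stdv`).
#' @param model a [pore_model()].
#' @param params a [scaling_params()].
#' @param transitions a `transition_model` from [build_neighbour_table()];
#'   its K must match the model's.
#' @param logemit optional precomputed [log_emission_matrix()] (the other
#'   emission arguments are then ignored).
#' @return list of class `posterior_set`: `loglik` (nats), `posterior`
#'   (n x S matrix, rows sum to 1), `shift_mass` (length-3 vector).
#' @export
forward_backward <- function(events, model, params = scaling_params(),
                             transitions = build_neighbour_table(K = model$K),
                             logemit = NULL) {
  if (is.null(logemit))
    logemit <- log_emission_matrix(events, model, params)
  if (nrow(logemit) < 1L) stop("need at least one event")
  res <- fb_core(t(logemit), transitions$nbr, transitions$logp,
                 transitions$frac0, transitions$frac1, transitions$frac2)
  res$shift_mass <- as.numeric(res$shift_mass)
  class(res) <- "posterior_set"
  res
}

#' Viterbi decoding of the most likely state path
#'
#' Max-product dynamic programming in log space over the truncated
#' neighbour structure, with uniform initial distribution. Ties are
#' resolved toward the numerically smallest predecessor state so decoding
#' is fully deterministic. The joint log-probability of the best path and
#' the observations is read from the last column of the DP matrix.
#'
#' @inheritParams forward_backward
#' @return list of class `decoded_path`: `path` (0-based state indices,
#'   one per event) and `logp` (joint log-probability, nats).
#' @export
viterbi <- function(events, model, params = scaling_params(),
                    transitions = build_neighbour_table(K = model$K),
                    logemit = NULL) {
  if (is.null(logemit))
    logemit <- log_emission_matrix(events, model, params)
  if (nrow(logemit) < 1L) stop("need at least one event")
  res <- viterbi_core(t(logemit), transitions$nbr, transitions$logp)
  res$path <- as.integer(res$path)
  class(res) <- "decoded_path"
  res
}
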