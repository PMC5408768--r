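#' Prior transition probability between two kmer states
#'
#' Full (untruncated) transition probability of the kmer-state chain. A
#' transition can stay in the same state (probability `p_stay`,
#' a segmentation over-split), step by one base (total probability
#' `p_step = 1 - p_stay - p_skip`, split uniformly over the 4 successors),
#' or advance by `i >= 2` bases via skips. Because longer skips can connect
#' the same pair of kmers in several ways, the probability sums a geometric
#' series in `p_skip1 = p_skip / (1 + p_skip)` (the probability of exactly
#' one skip) over all shift amounts, including a closed-form tail for
#' shifts of at least K, which reaches every state.
#'
#' This is the exact row-stochastic reference used to validate the
#' truncated neighbour table; rows sum to 1 analytically.
#'
#' @param k1,k2 kmer strings of common length K, or 0-based state indices
#'   when `K` is given.
#' @param p_stay,p_skip stay/skip probabilities (`p_stay + p_skip < 1`).
#' @param K kmer length, required when `k1`,`k2` are indices.
#' @return transition probability.
#' @export
transition_prob_full <- function(k1, k2, p_stay = 0.1, p_skip = 0.3,
                                 K = NULL) {
  if (is.character(k1)) {
    K <- nchar(k1)
    k1 <- kmer_index(k1); k2 <- kmer_index(k2)
  }
  stopifnot(!is.null(K), p_stay >= 0, p_skip >= 0, p_stay + p_skip < 1)
  p_step <- 1 - p_stay - p_skip
  p_skip1 <- p_skip / (1 + p_skip)
  p <- if (k1 == k2) p_stay else 0
  # shift i = 1..K-1: suffix(k1, K-i) must equal prefix(k2, K-i)
  for (i in seq_len(K - 1L)) {
    if (k1 %% 4^(K - i) == k2 %/% 4^i) {
      w <- if (i == 1L) p_step / 4 else p_skip1^(i - 1) / 4^i
      p <- p + w
    }
  }
  # tail: shifts >= K always match (empty overlap), spread over all 4^K k2
  p + p_skip1^(K - 1) / ((1 - p_skip1) * 4^K)
}

#' Minimum number of skips between two states
#'
#' The smallest number of skipped kmers (shift minus one) by which `k1` can
#' be followed by `k2` in a single transition; shift K (no overlap
#' required) always connects. A pure stay (`k1 == k2` at shift 0) does not
#' count as a skip and `k1 == k2` is only reported as 0 skips when the kmer
#' also overlaps itself at shift 1.
#'
#' @inheritParams transition_prob_full
#' @return integer: 0 for a plain step, `i-1` when the smallest connecting
#'   shift is `i >= 2`.
#' @export
min_skips <- function(k1, k2, K = NULL) {
  if (is.character(k1)) {
    K <- nchar(k1)
    k1 <- kmer_index(k1); k2 <- kmer_index(k2)
  }
  stopifnot(!is.null(K))
  for (i in seq_len(K)) {
    if (i == K || k1 %% 4^(K - i) == k2 %/% 4^i) return(i - 1L)
  }
}

#' Build the truncated sparse transition table
#'
#' For decoding and training, transitions involving more than one skip are
#' discarded: each state keeps at most 21 successors (itself, its 4
#' one-step successors, its 16 two-step successors; the sets overlap for
#' low-complexity kmers). Each kept successor receives the sum of its
#' stay / step / one-skip contributions and every row is renormalized to
#' sum to 1 so the truncated chain remains a proper HMM.
#'
#' @inheritParams transition_prob_full
#' @param K kmer length.
#' @return an object of class `transition_model` with elements `p_stay`,
#'   `p_skip`, `K`, and the sparse table: `nbr` (S x 21 matrix of 0-based
#'   successor indices, -1 padding), `logp` (matching log probabilities),
#'   and `frac0`,`frac1`,`frac2` (per-edge fractions of probability mass
#'   attributable to stay / step / one-skip, used by Baum-Welch).
#' @export
build_neighbour_table <- function(p_stay = 0.1, p_skip = 0.3, K = 6) {
  stopifnot(p_stay >= 0, p_skip >= 0, p_stay + p_skip < 1)
  p_step <- 1 - p_stay - p_skip
  p_skip1 <- p_skip / (1 + p_skip)
  ns <- nbr_structure(K)
  # per-edge contributions by shift class on the deduplicated layout
  p0 <- p_stay * ns$is_self
  p1 <- (p_step / 4) * ns$is_step
  p2 <- (p_skip1 / 16) * ns$is_skip
  tot <- p0 + p1 + p2
  row_tot <- p_stay + p_step + p_skip1   # analytic row sum pre-truncation
  logp <- log(tot) - log(row_tot)
  logp[ns$nbr < 0L] <- -Inf
  safe <- pmax(tot, .Machine$double.xmin)
  f0 <- p0 / safe; f1 <- p1 / safe; f2 <- p2 / safe
  structure(list(p_stay = p_stay, p_skip = p_skip,
                 p_step = p_step, p_skip1 = p_skip1, K = as.integer(K),
                 nbr = ns$nbr, logp = logp,
                 frac0 = f0, frac1 = f1, frac2 = f2),
            class = "transition_model")
}

# cache of the K-dependent sparse successor layout: 0-based successor
# indices (S x 21, -1 padded, duplicates merged per row) plus logical
# masks saying whether each edge can be reached as stay / step / one-skip
nbr_structure_cache <- new.env(parent = emptyenv())

nbr_structure <- function(K) {
  key <- as.character(K)
  if (!is.null(nbr_structure_cache[[key]])) return(nbr_structure_cache[[key]])
  S <- 4^K
  k <- 0:(S - 1)
  step_base <- (k %% 4^(K - 1)) * 4      # suffix(k, K-1) shifted left
  skip_base <- if (K >= 2) (k %% 4^(K - 2)) * 16 else rep(0, S)
  nbr <- matrix(-1L, S, 21)
  for (i in seq_len(S)) {
    succ <- sort(unique(c(k[i], step_base[i] + 0:3, skip_base[i] + 0:15)))
    nbr[i, seq_along(succ)] <- as.integer(succ)
  }
  is_self <- nbr == k                                  # recycles by column
  is_step <- (nbr %/% 4L) == (k %% 4^(K - 1))
  is_skip <- (nbr %/% 16L) == (k %% 4^(max(K - 2, 0)))
  pad <- nbr < 0L
  is_self[pad] <- FALSE; is_step[pad] <- FALSE; is_skip[pad] <- FALSE
  ns <- list(nbr = nbr, is_self = is_self, is_step = is_step,
             is_skip = is_skip)
  nbr_structure_cache[[key]] <- ns
  ns
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf(
    "transition_model: K=%d, p_stay=%.4f, p_skip=%.4f (<=%d neighbours)\n",
    x$K, x$p_stay, x$p_skip, max(rowSums(x$nbr >= 0))))
  invisible(x)
}

# Baum-Welch clamping bounds for p_stay / p_skip
TRANS_PROB_MIN <- 1e-4
TRANS_PROB_MAX <- 0.49

#' Baum-Welch update of the transition parameters
#'
#' Re-estimates `p_stay` and `p_skip` from the expected posterior
#' transition mass per shift class (stay / step / one skip) accumulated
#' by a forward-backward pass. In the truncated chain every row is
#' renormalized by the kept mass `Z = p_stay + p_step + p_skip1`, so the
#' observable class fractions are `p_stay/Z`, `p_step/Z`, `p_skip1/Z`;
#' the update inverts that mapping exactly: writing `f2` for the one-skip
#' mass fraction, `p_skip` solves the quadratic
#' `f2 p^2 + (1 - f2) p - f2 = 0` (from `p_skip1 = p/(1+p)` and
#' `Z = 1 - p^2/(1+p)`), and `p_stay` is the stay fraction times `Z`.
#' A naive ratio estimate that ignores `Z` is inconsistent: applied at
#' the true parameters it inflates `p_skip` and the iteration runs to its
#' bound. Both estimates are clamped to `[1e-4, 0.49]` to avoid
#' degenerate fixed points.
#'
#' @param masses numeric length-3 vector of nonnegative expected masses for
#'   shift classes 0 (stay), 1 (step), 2 (one skip).
#' @param current a `transition_model` (or list with `p_stay`, `p_skip`)
#'   returned unchanged when all masses are zero.
#' @return list with updated `p_stay`, `p_skip`.
#' @export
update_transition_params <- function(masses,
                                     current = list(p_stay = 0.1,
                                                    p_skip = 0.3)) {
  stopifnot(length(masses) == 3, all(masses >= 0))
  tot <- sum(masses)
  if (tot == 0)
    return(list(p_stay = current$p_stay, p_skip = current$p_skip))
  clamp <- function(p) min(max(p, TRANS_PROB_MIN), TRANS_PROB_MAX)
  f0 <- masses[1] / tot
  f2 <- masses[3] / tot
  p_skip <- if (f2 > 0) {
    (-(1 - f2) + sqrt((1 - f2)^2 + 4 * f2^2)) / (2 * f2)
  } else 0
  Z <- 1 - p_skip^2 / (1 + p_skip)
  list(p_stay = clamp(f0 * Z), p_skip = clamp(p_skip))
}
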