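# Shared fixtures and independent oracles for the test suite.

# run code under a private seeded RNG stream
seeded <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  code
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random DNA with no homopolymer run longer than maxrun. Exact-decode
# fixtures need this: the minimal-overlap sequence reconstruction caps
# output runs at K by design, so longer planted runs are unrepresentable.
random_dna_capped <- function(n, maxrun) {
  bases <- c("A", "C", "G", "T")
  s <- character(n)
  s[1] <- sample(bases, 1)
  run <- 1L
  for (i in 2:n) {
    pool <- if (run >= maxrun) setdiff(bases, s[i - 1]) else bases
    s[i] <- sample(pool, 1)
    run <- if (s[i] == s[i - 1]) run + 1L else 1L
  }
  paste(s, collapse = "")
}

# dense transition matrix (S x S) from a truncated transition_model
dense_transitions <- function(tbl) {
  S <- 4^tbl$K
  Tm <- matrix(0, S, S)
  for (i in seq_len(S)) {
    for (m in seq_len(ncol(tbl$nbr))) {
      j <- tbl$nbr[i, m]
      if (j >= 0) Tm[i, j + 1] <- exp(tbl$logp[i, m])
    }
  }
  Tm
}

# Brute-force oracle: enumerate every state path of length n and sum /
# maximize path-joint probabilities in the truncated HMM with uniform
# initial distribution. `logemit` is n x S. Independent of the DP code.
enumerate_paths <- function(logemit, Tm) {
  n <- nrow(logemit)
  S <- ncol(logemit)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  lp <- -log(S) + logemit[1, paths[, 1]]
  if (n > 1) {
    for (t in 2:n) {
      lp <- lp + log(Tm[cbind(paths[, t - 1], paths[, t])]) +
        logemit[t, paths[, t]]
    }
  }
  m <- max(lp)
  list(loglik = m + log(sum(exp(lp - m))),
       best_logp = m,
       best_path = paths[which.max(lp), ] - 1L,
       all_logp = lp, paths = paths)
}

# brute-force posterior of state j at event t from enumerated paths
enumerate_posterior <- function(enum) {
  w <- exp(enum$all_logp - enum$loglik)
  n <- ncol(enum$paths)
  S <- max(enum$paths)
  sapply(seq_len(S), function(j)
    sapply(seq_len(n), function(t) sum(w[enum$paths[, t] == j])))
}

# string-based overlap scanner used as min_skips oracle
min_skips_bf <- function(k1, k2) {
  K <- nchar(k1)
  for (i in seq_len(K)) {
    if (i == K ||
        substr(k1, i + 1, K) == substr(k2, 1, K - i))
      return(i - 1L)
  }
}

# untruncated transition probability by direct series evaluation over
# string overlaps (independent reimplementation of Eq-style recursion)
trans_full_bf <- function(k1, k2, p_stay, p_skip) {
  K <- nchar(k1)
  p_step <- 1 - p_stay - p_skip
  p_skip1 <- p_skip / (1 + p_skip)
  p <- if (k1 == k2) p_stay else 0
  for (i in seq_len(K - 1)) {
    if (substr(k1, i + 1, K) == substr(k2, 1, K - i)) {
      p <- p + if (i == 1) p_step / 4 else p_skip1^(i - 1) / 4^i
    }
  }
  p + p_skip1^(K - 1) / ((1 - p_skip1) * 4^K)
}

# simulate one strand of events with a given model/scaling (no hairpin)
sim_strand <- function(seed, model, scaling, n_bases = 1100,
                       p_stay = 0.1, p_skip = 0.05, noise = 1) {
  cfg <- sim_config(seed = seed, K = model$K, seq_len = n_bases,
                    p_stay = p_stay, p_skip = p_skip,
                    scaling = scaling, noise = noise)
  seeded(seed, {
    seq <- random_dna(n_bases)
    simulate_events(seq, model, cfg)
  })
}

# longest single-base run in a DNA string
max_homopolymer <- function(seq) {
  r <- rle(strsplit(seq, "")[[1]])
  max(r$lengths)
}
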