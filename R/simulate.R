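# Inverse Gaussian sampler, IG(mean = m, shape = lambda)
# (Michael-Schucany-Haas transformation method)
rinvgauss <- function(n, m, lambda) {
  y <- stats::rchisq(n, df = 1)
  x <- m + (m^2 * y - m * sqrt(4 * m * lambda * y + m^2 * y^2)) /
    (2 * lambda)
  u <- runif(n)
  ifelse(u <= m / (m + x), x, m^2 / x)
}

# run code with a private, seeded RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Simulation configuration
#'
#' Collects every knob of the generative model used to produce synthetic
#' reads: the kmer path dynamics (stays/skips), the per-read scaling
#' distortion, emission noise, and the abasic hairpin joining the two
#' strands. The single `seed` fixes all randomness end to end.
#'
#' @param seed integer RNG seed.
#' @param K kmer length.
#' @param seq_len template sequence length in bases.
#' @param p_stay,p_skip stay / skip probabilities of the event walk. The
#'   defaults (0.1 / 0.05) give about one event per base, as observed in
#'   real runs; note the decoder's prior default for `p_skip` is a more
#'   conservative 0.3. A high simulated skip rate shrinks reads below
#'   ~1000 events, where a 10-event island exceeds the 1% quantile
#'   headroom of the hairpin heuristic and splitting fails by design.
#' @param scaling true [scaling_params()] distorting the events. The
#'   default is a mild, realistic per-read distortion (a few pA of shift, a
#'   few percent of gain error, slow drift, slightly inflated noise).
#' @param noise emission-noise inflation factor: event means are drawn with
#'   standard deviation `noise * var * sigma_k` and event stdvs with IG
#'   shape `var_sd * gamma_k / noise^2`; `noise = 0` emits the exact scaled
#'   model values (a noise-free read).
#' @param abasic_level mean current of abasic hairpin events (pA, above the
#'   100 pA mark that separates abasic from regular DNA signal).
#' @param island_len number of abasic events in the hairpin island.
#' @param hairpin_pos fraction of the template sequence length at which the
#'   hairpin sits (0.5 = centred read).
#' @param event_rate expected events per second (event lengths are
#'   exponential with this rate).
#' @param hp_runs,hp_len number of homopolymer runs of length `hp_len`
#'   planted in the template sequence (size-1 repeats are where the
#'   minimal-overlap sequence reconstruction is known to compress).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, K = 6L, seq_len = 500L,
                       p_stay = 0.1, p_skip = 0.05,
                       scaling = scaling_params(shift = 5, scale = 1.02,
                                                drift = 0.02, var = 1.2,
                                                scale_sd = 1.05,
                                                var_sd = 1.1),
                       noise = 1, abasic_level = 110, island_len = 10L,
                       hairpin_pos = 0.5, event_rate = 30,
                       hp_runs = 2L, hp_len = 10L) {
  stopifnot(K >= 1, seq_len >= K, p_stay >= 0, p_skip >= 0,
            p_stay + p_skip < 1, noise >= 0, event_rate > 0)
  structure(list(seed = as.integer(seed), K = as.integer(K),
                 seq_len = as.integer(seq_len), p_stay = p_stay,
                 p_skip = p_skip, scaling = scaling, noise = noise,
                 abasic_level = abasic_level,
                 island_len = as.integer(island_len),
                 hairpin_pos = hairpin_pos, event_rate = event_rate,
                 hp_runs = as.integer(hp_runs), hp_len = as.integer(hp_len)),
            class = "sim_config")
}

#' Simulate a pore model
#'
#' Draws a synthetic per-kmer emission table: level means are a random
#' permutation of a jittered grid spanning the 50-90 pA range of regular
#' DNA (guaranteeing no two kmers collide), level stdvs in [0.5, 2] pA,
#' IG means in [1, 3] pA and IG shapes in [3, 10]. Deterministic per seed.
#'
#' @param seed integer RNG seed.
#' @param K kmer length.
#' @param name model label.
#' @return a [pore_model()].
#' @export
simulate_pore_model <- function(seed, K = 6L, name = "template") {
  S <- 4^K
  with_seed(seed, {
    gap <- 40 / S
    levels <- seq(50 + gap / 2, 90 - gap / 2, length.out = S) +
      runif(S, -0.45, 0.45) * gap
    pore_model(level_mean = sample(levels),
               level_stdv = runif(S, 0.5, 2),
               sd_mean = runif(S, 1, 3),
               sd_stdv = runif(S, 3, 10),
               name = name, K = K)
  })
}

# random DNA sequence with optional planted homopolymer runs
simulate_sequence <- function(seq_len, hp_runs = 0L, hp_len = 10L) {
  s <- sample(DNA_BASES, seq_len, replace = TRUE)
  if (hp_runs > 0L && seq_len >= hp_len) {
    slots <- floor(seq(1, seq_len - hp_len + 1,
                       length.out = hp_runs + 2))[2:(hp_runs + 1)]
    for (p in slots) s[p:(p + hp_len - 1L)] <- sample(DNA_BASES, 1)
  }
  paste(s, collapse = "")
}

# sample one shift: 0 w.p. p_stay, 1 w.p. p_step, d>=2 geometric in p_skip1
sample_shift <- function(p_stay, p_skip) {
  u <- runif(1)
  if (u < p_stay) return(0L)
  if (u < p_stay + (1 - p_stay - p_skip)) return(1L)
  p_skip1 <- p_skip / (1 + p_skip)
  2L + stats::rgeom(1, 1 - p_skip1)
}

#' Simulate an event sequence from a DNA sequence
#'
#' Walks the kmer chain of `sequence`, at each move staying with
#' probability `p_stay`, stepping one base, or skipping ahead (skip count
#' geometric in `p_skip1 = p_skip/(1+p_skip)`, mirroring the transition
#' prior). Each visited state emits one event: the mean from the scaled
#' Gaussian, the stdv from the scaled Inverse Gaussian, with start times
#' accumulating exponential event lengths.
#'
#' @param sequence DNA string (length >= K).
#' @param model a [pore_model()].
#' @param config a [sim_config()]; its `seed` is NOT applied here (wrap in
#'   a seeded context or use [simulate_read()]), so the walk can be
#'   composed into larger simulations.
#' @param t0 start time of the first event (s).
#' @return list: `events` data.frame, `path` (0-based true state per
#'   event), `shifts` (true shift class per transition, length n-1).
#' @export
simulate_events <- function(sequence, model, config, t0 = 0) {
  K <- model$K
  stopifnot(nchar(sequence) >= K)
  kmers <- substring(sequence, 1:(nchar(sequence) - K + 1),
                     K:nchar(sequence))
  states <- kmer_index(kmers)
  n_pos <- length(states)
  pos <- 1L
  path <- integer(2L * n_pos + 16L)
  shifts <- integer(2L * n_pos + 16L)
  n <- 0L
  repeat {
    n <- n + 1L
    if (n > length(path)) {         # long stay streak: grow buffers
      path <- c(path, integer(length(path)))
      shifts <- c(shifts, integer(length(shifts)))
    }
    path[n] <- states[pos]
    if (pos >= n_pos) break
    d <- sample_shift(config$p_stay, config$p_skip)
    d <- min(d, n_pos - pos)
    shifts[n] <- d
    pos <- pos + d
  }
  path <- path[seq_len(n)]
  shifts <- shifts[seq_len(n - 1L)]
  len <- rexp(n, rate = config$event_rate)
  start <- t0 + cumsum(c(0, len[-n]))
  s <- config$scaling
  i <- path + 1L
  gmean <- s$scale * model$level_mean[i] + s$shift + s$drift * start
  gsd <- config$noise * s$var * model$level_stdv[i]
  mean <- if (config$noise > 0) rnorm(n, gmean, gsd) else gmean
  igm <- s$scale_sd * model$sd_mean[i]
  stdv <- if (config$noise > 0) {
    rinvgauss(n, igm, s$var_sd * model$sd_stdv[i] / config$noise^2)
  } else igm
  list(events = data.frame(start = start, length = len,
                           mean = mean, stdv = stdv),
       path = path, shifts = shifts)
}

#' Simulate a full two-strand read
#'
#' Produces a complete synthetic read under the generative model: template
#' events from a random sequence, an abasic hairpin island (event means
#' around `abasic_level`), and complement events from the
#' reverse-complement sequence under a second pore model. All randomness is
#' fixed by `config$seed`.
#'
#' @param config a [sim_config()].
#' @param template_model,complement_model [pore_model()]s for the two
#'   strands; simulated from `config$seed` by default.
#' @return list of class `sim_read`: `events` (full event data.frame),
#'   `truth` (list: `template_seq`, `complement_seq`, `island` 1-based
#'   half-open interval or NULL, `scaling`, `p_stay`, `p_skip`, per-strand
#'   true paths), and the two models.
#' @export
simulate_read <- function(config = sim_config(),
                          template_model = NULL, complement_model = NULL) {
  if (is.null(template_model))
    template_model <- simulate_pore_model(config$seed + 104729L,
                                          config$K, "template")
  if (is.null(complement_model))
    complement_model <- simulate_pore_model(config$seed + 224737L,
                                            config$K, "complement_1")
  with_seed(config$seed, {
    # hairpin_pos sets where the island falls in the read: the template
    # carries that fraction of the total bases, the complement (the
    # reverse complement of the template, truncated or padded as when a
    # strand exits the pore early/late) carries the rest
    total <- 2L * config$seq_len
    lt <- max(config$K, min(total - config$K,
                            as.integer(round(total * config$hairpin_pos))))
    lc <- total - lt
    tseq <- simulate_sequence(lt, config$hp_runs, config$hp_len)
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(tseq, "")[[1]]), collapse = ""))
    cseq <- if (lc <= lt) substr(rc, 1, lc)
            else paste0(rc, simulate_sequence(lc - lt))
    tem <- simulate_events(tseq, template_model, config, t0 = 0)
    t_end <- with(tem$events, start[nrow(tem$events)] +
                                length[nrow(tem$events)])
    ni <- config$island_len
    island_events <- NULL
    c_start <- t_end
    if (ni > 0L) {
      ilen <- rexp(ni, rate = config$event_rate)
      istart <- t_end + cumsum(c(0, ilen[-ni]))
      island_events <- data.frame(
        start = istart, length = ilen,
        mean = rnorm(ni, config$abasic_level, 1),
        stdv = rinvgauss(ni, 2, 8))
      c_start <- istart[ni] + ilen[ni]
    }
    com <- simulate_events(cseq, complement_model, config, t0 = c_start)
    events <- rbind(tem$events, island_events, com$events)
    rownames(events) <- NULL
    nt <- nrow(tem$events)
    island <- if (ni > 0L) c(nt + 1L, nt + ni + 1L) else NULL
    structure(list(
      events = events,
      truth = list(template_seq = tseq, complement_seq = cseq,
                   island = island, scaling = config$scaling,
                   p_stay = config$p_stay, p_skip = config$p_skip,
                   template_path = tem$path, complement_path = com$path),
      template_model = template_model,
      complement_model = complement_model,
      config = config), class = "sim_read")
  })
}

#' Alignment identity against a known truth sequence
#'
#' Aligns the called sequence to the truth globally (match +1, mismatch -1,
#' gap -1, end gaps on the truth free) and returns match columns divided by
#' called bases aligned plus truth bases deleted — i.e. matches over all
#' alignment columns of the aligned region.
#'
#' @param called,truth nonempty DNA strings.
#' @return identity fraction in [0, 1].
#' @export
alignment_identity <- function(called, truth) {
  if (!nzchar(called) || !nzchar(truth)) stop("sequences must be nonempty")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(
    pattern = called, subject = truth, type = "global-local",
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- sum(p == s & p != "-")
  aligned_called <- sum(p != "-")
  deleted_truth <- sum(p == "-" & s != "-")
  matches / (aligned_called + deleted_truth)
}
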