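#' Training configuration
#'
#' Controls the per-read scaling/transition training. `num_events` events
#' are taken from the start and from the end of each strand (the two
#' subsets are treated as independent chains); EM stops after `max_rounds`
#' rounds (default 10 in single-strand mode, 20 in double-strand mode) or
#' when the log-likelihood gain of a round drops below `min_progress` nats
#' (1 nat = a multiplicative likelihood factor of e).
#'
#' @param num_events events taken from each end of each strand.
#' @param max_rounds maximum EM rounds per strand (NULL = mode default).
#' @param min_progress minimum log-likelihood gain (nats) to continue.
#' @param train_transitions refit `p_stay`/`p_skip` by Baum-Welch each
#'   round.
#' @param mode `"double_strand"` (one shared set of scaling parameters per
#'   read, pooled M-step) or `"single_strand"` (each strand independent).
#' @param no_train skip EM entirely: Method-of-Moments scaling only.
#' @param p_stay,p_skip initial transition parameters.
#' @return list of class `training_config`.
#' @export
training_config <- function(num_events = 100L, max_rounds = NULL,
                            min_progress = 1.0, train_transitions = TRUE,
                            mode = c("double_strand", "single_strand"),
                            no_train = FALSE,
                            p_stay = 0.1, p_skip = 0.3) {
  mode <- match.arg(mode)
  if (is.null(max_rounds))
    max_rounds <- if (mode == "double_strand") 20L else 10L
  stopifnot(num_events >= 1, max_rounds >= 0, min_progress >= 0)
  structure(list(num_events = as.integer(num_events),
                 max_rounds = as.integer(max_rounds),
                 min_progress = min_progress,
                 train_transitions = isTRUE(train_transitions),
                 mode = mode, no_train = isTRUE(no_train),
                 p_stay = p_stay, p_skip = p_skip),
            class = "training_config")
}

#' Method-of-Moments scaling initialization
#'
#' Matches the first two moments of the observed event means to the
#' moments of the pore-model kmer levels, assuming visited states are
#' roughly uniform over kmers: `scale = sd(means)/sd(mu)` and
#' `shift = mean(means) - scale*mean(mu)`. Only shift and scale are
#' estimated; the remaining four parameters stay neutral. Events above the
#' read's abasic threshold are excluded so a residual hairpin signal does
#' not bias the moments.
#'
#' @param events data.frame of events.
#' @param model a [pore_model()].
#' @return a [scaling_params()].
#' @export
mom_init <- function(events, model) {
  if (nrow(events) < 1L) stop("need at least one event")
  keep <- events$mean <= abasic_threshold(events)
  x <- events$mean[keep]
  if (length(x) < 2L || sd(x) == 0) {
    return(scaling_params(shift = mean(x) - mean(model$level_mean),
                          scale = 1))
  }
  scale <- sd(x) / sd(model$level_mean)
  scaling_params(shift = mean(x) - scale * mean(model$level_mean),
                 scale = scale)
}

# Pooled sufficient statistics from forward-backward posteriors, for the
# emission M-step. `chains` is a list of event data.frames treated as
# independent chains (no transition bridges the gap between them).
fb_stats <- function(chains, model, transitions, params) {
  sg2 <- model$level_stdv^2
  v_a <- 1 / sg2
  v_b <- model$level_mean / sg2
  v_c <- model$level_mean^2 / sg2
  v_ge <- model$sd_stdv / model$sd_mean^2    # gamma / eta^2
  v_gn <- model$sd_stdv / model$sd_mean      # gamma / eta
  v_g <- model$sd_stdv
  st <- list(S_a = 0, S_at = 0, S_att = 0, S_b = 0, S_bt = 0, S_c = 0,
             S_am = 0, S_amt = 0, S_bm = 0, S_amm = 0,
             A = 0, B = 0, D = 0, N = 0,
             loglik = 0, shift_mass = c(0, 0, 0))
  for (ev in chains) {
    if (nrow(ev) == 0L) next
    fb <- forward_backward(ev, model, params, transitions)
    W <- fb$posterior
    a <- drop(W %*% v_a); b <- drop(W %*% v_b); cc <- drop(W %*% v_c)
    t <- ev$start; m <- ev$mean
    x <- pmax(ev$stdv, STDV_FLOOR)
    st$S_a <- st$S_a + sum(a)
    st$S_at <- st$S_at + sum(a * t)
    st$S_att <- st$S_att + sum(a * t^2)
    st$S_b <- st$S_b + sum(b)
    st$S_bt <- st$S_bt + sum(b * t)
    st$S_c <- st$S_c + sum(cc)
    st$S_am <- st$S_am + sum(a * m)
    st$S_amt <- st$S_amt + sum(a * m * t)
    st$S_bm <- st$S_bm + sum(b * m)
    st$S_amm <- st$S_amm + sum(a * m^2)
    st$A <- st$A + sum(x * drop(W %*% v_ge))
    st$B <- st$B + sum(drop(W %*% v_gn))
    st$D <- st$D + sum(drop(W %*% v_g) / x)
    st$N <- st$N + nrow(ev)
    st$loglik <- st$loglik + fb$loglik
    st$shift_mass <- st$shift_mass + fb$shift_mass
  }
  st
}

# Emission M-step from pooled sufficient statistics: weighted least
# squares for (scale, shift, drift), closed-form var, and the exact
# first-order-condition solutions for the IG pair (scale_sd = A/B,
# var_sd from the stationarity of the expected IG log-likelihood).
m_step <- function(st, prev) {
  XtX <- matrix(c(st$S_c, st$S_b, st$S_bt,
                  st$S_b, st$S_a, st$S_at,
                  st$S_bt, st$S_at, st$S_att), 3, 3)
  Xty <- c(st$S_bm, st$S_am, st$S_amt)
  beta <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
  if (is.null(beta) || !all(is.finite(beta)) || beta[1] <= 0)
    return(prev)
  scale <- beta[1]; shift <- beta[2]; drift <- beta[3]
  sse <- st$S_amm - 2 * (scale * st$S_bm + shift * st$S_am +
                           drift * st$S_amt) +
    scale^2 * st$S_c + shift^2 * st$S_a + drift^2 * st$S_att +
    2 * (scale * shift * st$S_b + scale * drift * st$S_bt +
           shift * drift * st$S_at)
  var2 <- sse / st$N
  scale_sd <- st$A / st$B
  if (!is.finite(scale_sd) || scale_sd <= 0) scale_sd <- prev$scale_sd
  C <- st$A / scale_sd^2 - 2 * st$B / scale_sd + st$D
  var_sd <- st$N / C
  if (!all(is.finite(c(var2, var_sd))) || var2 <= 0 || var_sd <= 0)
    return(prev)
  scaling_params(shift = shift, scale = scale, drift = drift,
                 var = sqrt(var2), scale_sd = scale_sd, var_sd = var_sd)
}

#' One EM round of scaling training
#'
#' E-step: forward-backward posteriors under the current parameters on the
#' given events (a data.frame, or a list of data.frames treated as
#' independent chains). M-step: maximize the expected complete-data log
#' emission likelihood — weighted least squares for (scale, shift, drift),
#' closed-form `var`, and the first-order-condition solutions for
#' (`scale_sd`, `var_sd`).
#'
#' @param events event data.frame or list of data.frames (chains).
#' @param model a [pore_model()].
#' @param transitions a `transition_model`.
#' @param params current [scaling_params()].
#' @return list: `params` (updated), `loglik` (of the E-step, i.e. under
#'   the incoming parameters), `shift_mass` (for Baum-Welch).
#' @export
em_round <- function(events, model, transitions, params) {
  chains <- if (is.data.frame(events)) list(events) else events
  st <- fb_stats(chains, model, transitions, params)
  if (!is.finite(st$loglik)) {
    warning("non-finite likelihood; keeping previous parameters")
    return(list(params = params, loglik = st$loglik,
                shift_mass = st$shift_mass))
  }
  list(params = m_step(st, params), loglik = st$loglik,
       shift_mass = st$shift_mass)
}

# Moment-based drift initialization. MoM proper leaves drift at 0, but EM
# started there crawls along a shift/drift/state-assignment ridge (dense
# kmer levels let posterior reassignment absorb a time trend almost
# perfectly, so per-round gains are tiny). The start- and end-subset mean
# levels identify drift directly: their difference over the time gap is
# drift times Delta-t under uniform state sampling, the same assumption
# MoM already makes. Shift is re-centred accordingly.
init_drift <- function(params, chains, model = NULL, transitions = NULL) {
  if (length(chains) < 2L) return(params)
  m1 <- mean(chains[[1]]$mean); m2 <- mean(chains[[2]]$mean)
  dt <- mean(chains[[2]]$start) - mean(chains[[1]]$start)
  if (!is.finite(dt) || dt <= 0) return(params)
  d0 <- (m2 - m1) / dt
  tmid <- mean(c(chains[[1]]$start, chains[[2]]$start))
  shift0 <- params$shift
  at_drift <- function(d) {
    p <- params
    p$drift <- d
    p$shift <- shift0 - d * tmid
    p
  }
  if (is.null(model)) return(at_drift(d0))
  # the moment contrast carries kmer-sampling noise with standard error
  # lev_sd * sqrt(2/n) / dt, comparable to realistic drifts; score a
  # +-2 SE grid by forward likelihood and start EM from the best point
  n <- min(nrow(chains[[1]]), nrow(chains[[2]]))
  se <- sd(c(chains[[1]]$mean, chains[[2]]$mean)) * sqrt(2 / n) / dt
  cands <- d0 + se * (-2:2)
  liks <- vapply(cands, function(d) {
    p <- at_drift(d)
    sum(vapply(chains, function(ch)
      forward_loglik_core(t(log_emission_matrix(ch, model, p)),
                          transitions$nbr, transitions$logp), 0))
  }, 0)
  at_drift(cands[which.max(liks)])
}

# training subsets: num_events from the start and num_events from the end
# of a strand, as independent chains; a short strand is one single chain.
# Start times are re-zeroed per strand before any fitting.
training_chains <- function(events, num_events) {
  events$start <- events$start - events$start[1]
  n <- nrow(events)
  if (n <= 2 * num_events) return(list(events))
  list(events[seq_len(num_events), , drop = FALSE],
       events[(n - num_events + 1L):n, , drop = FALSE])
}

MODEL_SELECT_MARGIN <- 20  # nats; multiplicative likelihood factor e^20

#' Train scaling and transition parameters for one read
#'
#' Runs the full per-read training: the read is split into strands, each
#' strand gets a Method-of-Moments initialization, then EM rounds update
#' the six scaling parameters (and, optionally, `p_stay`/`p_skip` by
#' Baum-Welch) until the round budget is exhausted or the likelihood gain
#' falls below `min_progress`. In double-strand mode one shared set of
#' scaling parameters is fit per complement-model candidate by pooling the
#' M-step statistics of both strands; in single-strand mode every
#' (strand, model) pair trains independently. Whenever one complement
#' model's likelihood exceeds every other candidate's by more than 20 nats
#' (factor e^20), that model is selected immediately.
#'
#' @param events full event data.frame of the read.
#' @param models list of [pore_model()]s: the one named `"template"` (or
#'   the first) serves the template strand, all others are complement
#'   candidates.
#' @param config a [training_config()].
#' @param split optional precomputed [split_read()] result.
#' @return list of class `read_training`: per-strand candidate lists (each
#'   candidate: `model`, `params`, `p_stay`, `p_skip`, `loglik`, `rounds`),
#'   `selected_complement` (model name or NA), plus the `split` used.
#' @export
train_read <- function(events, models, config = training_config(),
                       split = NULL) {
  if (is.null(split)) split <- split_read(events)
  roles <- model_roles(models)
  tem_ev <- strand_events(events, split$template_range)
  com_ev <- strand_events(events, split$complement_range)
  has_complement <- !is.null(split$complement_range)
  if (has_complement && nrow(com_ev) == 0L) {
    warning("empty complement segment after split; template-only read")
    has_complement <- FALSE
  }
  if (nrow(tem_ev) == 0L) {
    warning("empty template segment; neutral parameters")
    tem_ev <- NULL
  }

  out <- structure(list(split = split, mode = config$mode,
                        template = NULL, complement = NULL,
                        selected_complement = NA_character_),
                   class = "read_training")

  candidate <- function(model, ev, chains = NULL) {
    params <- if (is.null(ev)) scaling_params() else mom_init(ev, model)
    if (!is.null(chains)) {
      tbl <- build_neighbour_table(config$p_stay, config$p_skip, model$K)
      params <- init_drift(params, chains, model, tbl)
    }
    list(model = model, params = params,
         p_stay = config$p_stay, p_skip = config$p_skip,
         loglik = NA_real_, rounds = 0L, active = TRUE)
  }
  tmod <- roles$template
  cmods <- roles$complement

  if (config$no_train || config$max_rounds == 0L || is.null(tem_ev)) {
    out$template <- list(candidate(tmod, tem_ev))
    if (has_complement)
      out$complement <- lapply(cmods, candidate, ev = com_ev)
    return(out)
  }

  t_chains <- training_chains(tem_ev, config$num_events)
  c_chains <- if (has_complement)
    training_chains(com_ev, config$num_events) else NULL

  if (config$mode == "double_strand" && has_complement) {
    out <- train_double(out, tmod, cmods, t_chains, c_chains,
                        tem_ev, com_ev, config)
  } else {
    out$template <- train_single_strand(
      list(candidate(tmod, tem_ev, t_chains)), t_chains, config)
    if (has_complement) {
      cands <- train_single_strand(
        lapply(cmods, candidate, ev = com_ev, chains = c_chains),
        c_chains, config)
      out$complement <- cands
      out$selected_complement <- attr(cands, "selected")
    }
  }
  out
}

# EM loop for one strand, possibly several model candidates (complement);
# applies the e^20 selection margin after every round.
train_single_strand <- function(cands, chains, config) {
  selected <- NA_character_
  for (r in seq_len(config$max_rounds)) {
    for (i in seq_along(cands)) {
      cd <- cands[[i]]
      if (!cd$active) next
      tbl <- build_neighbour_table(cd$p_stay, cd$p_skip, cd$model$K)
      em <- em_round(chains, cd$model, tbl, cd$params)
      gain <- em$loglik - cd$loglik
      cd$params <- em$params
      if (config$train_transitions) {
        up <- update_transition_params(em$shift_mass, cd)
        cd$p_stay <- up$p_stay; cd$p_skip <- up$p_skip
      }
      cd$rounds <- r
      if (!is.na(cd$loglik) && (!is.finite(gain) ||
                                gain < config$min_progress))
        cd$active <- FALSE
      cd$loglik <- em$loglik
      cands[[i]] <- cd
    }
    if (length(cands) > 1L && is.na(selected)) {
      ll <- vapply(cands, `[[`, numeric(1), "loglik")
      if (!anyNA(ll)) {
        top <- which.max(ll)
        if (ll[top] - max(ll[-top]) > MODEL_SELECT_MARGIN) {
          selected <- cands[[top]]$model$name
          for (i in seq_along(cands)[-top]) cands[[i]]$active <- FALSE
        }
      }
    }
    if (!any(vapply(cands, `[[`, logical(1), "active"))) break
  }
  attr(cands, "selected") <- selected
  cands
}

# double-strand training: one shared ScalingParams per complement
# candidate, pooled M-step over both strands (each under its own model);
# transitions still trained per strand.
train_double <- function(out, tmod, cmods, t_chains, c_chains,
                         tem_ev, com_ev, config) {
  tbl0_t <- build_neighbour_table(config$p_stay, config$p_skip, tmod$K)
  mom_t <- init_drift(mom_init(tem_ev, tmod), t_chains, tmod, tbl0_t)
  combos <- lapply(cmods, function(cm) {
    tbl0_c <- build_neighbour_table(config$p_stay, config$p_skip, cm$K)
    mom_c <- init_drift(mom_init(com_ev, cm), c_chains, cm, tbl0_c)
    params <- scaling_params(shift = (mom_t$shift + mom_c$shift) / 2,
                             scale = (mom_t$scale + mom_c$scale) / 2,
                             drift = (mom_t$drift + mom_c$drift) / 2)
    list(cmodel = cm, params = params,
         t_stay = config$p_stay, t_skip = config$p_skip,
         c_stay = config$p_stay, c_skip = config$p_skip,
         loglik = NA_real_, lik_t = NA_real_, lik_c = NA_real_,
         rounds = 0L, active = TRUE)
  })
  selected <- NA_character_
  for (r in seq_len(config$max_rounds)) {
    for (i in seq_along(combos)) {
      cb <- combos[[i]]
      if (!cb$active) next
      tbl_t <- build_neighbour_table(cb$t_stay, cb$t_skip, tmod$K)
      tbl_c <- build_neighbour_table(cb$c_stay, cb$c_skip, cb$cmodel$K)
      st_t <- fb_stats(t_chains, tmod, tbl_t, cb$params)
      st_c <- fb_stats(c_chains, cb$cmodel, tbl_c, cb$params)
      lik <- st_t$loglik + st_c$loglik
      if (!is.finite(lik)) { cb$active <- FALSE; combos[[i]] <- cb; next }
      pooled <- mapply(function(a, b) if (is.numeric(a)) a + b else a,
                       st_t, st_c, SIMPLIFY = FALSE)
      gain <- lik - cb$loglik
      cb$params <- m_step(pooled, cb$params)
      if (config$train_transitions) {
        up <- update_transition_params(st_t$shift_mass,
                                       list(p_stay = cb$t_stay,
                                            p_skip = cb$t_skip))
        cb$t_stay <- up$p_stay; cb$t_skip <- up$p_skip
        up <- update_transition_params(st_c$shift_mass,
                                       list(p_stay = cb$c_stay,
                                            p_skip = cb$c_skip))
        cb$c_stay <- up$p_stay; cb$c_skip <- up$p_skip
      }
      cb$rounds <- r
      if (!is.na(cb$loglik) && gain < config$min_progress)
        cb$active <- FALSE
      cb$loglik <- lik; cb$lik_t <- st_t$loglik; cb$lik_c <- st_c$loglik
      combos[[i]] <- cb
    }
    if (length(combos) > 1L && is.na(selected)) {
      ll <- vapply(combos, `[[`, numeric(1), "lik_c")
      if (!anyNA(ll)) {
        top <- which.max(ll)
        if (ll[top] - max(ll[-top]) > MODEL_SELECT_MARGIN) {
          selected <- combos[[top]]$cmodel$name
          for (i in seq_along(combos)[-top]) combos[[i]]$active <- FALSE
        }
      }
    }
    if (!any(vapply(combos, `[[`, logical(1), "active"))) break
  }
  # best combo (selected model if any, else highest total likelihood)
  ll <- vapply(combos, `[[`, numeric(1), "loglik")
  best <- if (!is.na(selected))
    which(vapply(combos, function(cb) cb$cmodel$name, "") == selected)
  else which.max(ll)
  out$template <- list(list(model = tmod,
                            params = combos[[best]]$params,
                            p_stay = combos[[best]]$t_stay,
                            p_skip = combos[[best]]$t_skip,
                            loglik = combos[[best]]$lik_t,
                            rounds = combos[[best]]$rounds,
                            active = FALSE))
  out$complement <- lapply(combos, function(cb)
    list(model = cb$cmodel, params = cb$params,
         p_stay = cb$c_stay, p_skip = cb$c_skip,
         loglik = cb$lik_c, rounds = cb$rounds, active = FALSE))
  out$selected_complement <- selected
  out
}

# classify a model list into template model + complement candidates
model_roles <- function(models) {
  if (inherits(models, "pore_model")) models <- list(models)
  stopifnot(length(models) >= 1)
  names <- vapply(models, `[[`, "", "name")
  it <- which(grepl("^template", names))
  it <- if (length(it)) it[1] else 1L
  comp <- models[-it]
  if (!length(comp)) comp <- models[it]   # same model serves both strands
  list(template = models[[it]], complement = comp)
}
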