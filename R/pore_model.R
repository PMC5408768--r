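#' @useDynLib porecall, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm rnorm runif rexp sd setNames
#' @importFrom utils read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Convert kmers to state indices and back
#'
#' States of the basecalling HMM are DNA kmers encoded in base 4 with
#' `A=0, C=1, G=2, T=3`, leftmost base most significant, giving indices in
#' `[0, 4^K)` in lexicographic kmer order.
#'
#' @param kmer character vector of DNA strings (single common length K).
#' @return `kmer_index`: integer vector of 0-based state indices.
#' @export
kmer_index <- function(kmer) {
  if (length(kmer) == 0L) return(integer(0))
  K <- unique(nchar(kmer))
  if (length(K) != 1L) stop("all kmers must have the same length")
  mat <- matrix(match(unlist(strsplit(kmer, "", fixed = TRUE)), DNA_BASES),
                nrow = K)
  if (anyNA(mat)) stop("kmer contains a non-ACGT character")
  as.integer(colSums((mat - 1L) * 4^((K - 1L):0L)))
}

#' @rdname kmer_index
#' @param idx integer vector of 0-based state indices.
#' @param K kmer length.
#' @return `index_kmer`: character vector of kmers.
#' @export
index_kmer <- function(idx, K) {
  if (any(idx < 0L | idx >= 4^K)) stop("state index out of range")
  out <- matrix("", nrow = K, ncol = length(idx))
  rem <- as.integer(idx)
  for (p in K:1) {
    out[p, ] <- DNA_BASES[rem %% 4L + 1L]
    rem <- rem %/% 4L
  }
  apply(out, 2, paste, collapse = "")
}

#' Construct a pore model
#'
#' A pore model gives, for every kmer, the parameters of the event-level
#' emission distributions: a Gaussian `N(level_mean, level_stdv^2)` for the
#' event mean and an Inverse Gaussian `IG(sd_mean, sd_stdv)` (mean, shape)
#' for the event standard deviation.
#'
#' @param level_mean,level_stdv,sd_mean,sd_stdv numeric vectors of length
#'   `4^K` in lexicographic kmer order (`level_stdv`, `sd_mean`, `sd_stdv`
#'   strictly positive).
#' @param name model label, e.g. `"template"` or `"complement_1"`.
#' @param K kmer length; inferred from the vector length by default.
#' @return an object of class `pore_model`.
#' @export
pore_model <- function(level_mean, level_stdv, sd_mean, sd_stdv,
                       name = "template", K = NULL) {
  n <- length(level_mean)
  if (is.null(K)) {
    K <- as.integer(round(log(n, 4)))
  }
  if (4^K != n) stop("need exactly 4^K kmer records, got ", n)
  if (length(level_stdv) != n || length(sd_mean) != n || length(sd_stdv) != n)
    stop("all parameter vectors must have length 4^K")
  if (any(!is.finite(level_mean)) || any(!is.finite(level_stdv)) ||
      any(!is.finite(sd_mean)) || any(!is.finite(sd_stdv)))
    stop("pore model parameters must be finite")
  if (any(level_stdv <= 0) || any(sd_mean <= 0) || any(sd_stdv <= 0))
    stop("level_stdv, sd_mean and sd_stdv must be strictly positive")
  structure(list(name = name, K = as.integer(K),
                 level_mean = as.numeric(level_mean),
                 level_stdv = as.numeric(level_stdv),
                 sd_mean = as.numeric(sd_mean),
                 sd_stdv = as.numeric(sd_stdv)),
            class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf("pore_model '%s': K=%d (%d kmers), levels %.1f-%.1f pA\n",
              x$name, x$K, 4^x$K, min(x$level_mean), max(x$level_mean)))
  invisible(x)
}

#' Per-read scaling parameters
#'
#' The six per-read (or per-strand) distortion parameters relating a pore
#' model to the observed events: for event i in state k,
#' `mean_i ~ N(scale*mu_k + shift + drift*start_i, (var*sigma_k)^2)` and
#' `stdv_i ~ IG(scale_sd*eta_k, var_sd*gamma_k)`.
#'
#' @param shift additive offset (pA).
#' @param scale multiplicative level scaling (dimensionless, > 0).
#' @param drift linear current drift over time (pA/s).
#' @param var inflation of the level noise (dimensionless, > 0).
#' @param scale_sd scaling of the IG mean (dimensionless, > 0).
#' @param var_sd scaling of the IG shape (dimensionless, > 0).
#' @return an object of class `scaling_params`. Defaults are the neutral
#'   element (no distortion).
#' @export
scaling_params <- function(shift = 0, scale = 1, drift = 0, var = 1,
                           scale_sd = 1, var_sd = 1) {
  if (scale <= 0 || var <= 0 || scale_sd <= 0 || var_sd <= 0)
    stop("scale, var, scale_sd and var_sd must be strictly positive")
  structure(list(shift = shift, scale = scale, drift = drift, var = var,
                 scale_sd = scale_sd, var_sd = var_sd),
            class = "scaling_params")
}

#' @export
print.scaling_params <- function(x, ...) {
  cat(sprintf(paste0("scaling_params: shift=%.3f scale=%.4f drift=%.5f ",
                     "var=%.4f scale_sd=%.4f var_sd=%.4f\n"),
              x$shift, x$scale, x$drift, x$var, x$scale_sd, x$var_sd))
  invisible(x)
}

#' Scaled emission parameters for one state
#'
#' Applies the per-read scaling to a pore model entry, at a given event
#' start time (the drift term is time dependent).
#'
#' @param model a [pore_model()].
#' @param k 0-based state index (may be a vector).
#' @param s a [scaling_params()].
#' @param t event start time in seconds (scalar or same length as `k`).
#' @return list with `mean`, `sd` (Gaussian) and `ig_mean`, `ig_shape`
#'   (Inverse Gaussian), each the length of `k`.
#' @export
scaled_params <- function(model, k, s, t = 0) {
  if (any(k < 0L | k >= 4^model$K)) stop("state index out of range")
  i <- k + 1L
  list(mean = s$scale * model$level_mean[i] + s$shift + s$drift * t,
       sd = s$var * model$level_stdv[i],
       ig_mean = s$scale_sd * model$sd_mean[i],
       ig_shape = s$var_sd * model$sd_stdv[i])
}

# log density of the Inverse Gaussian IG(mean = m, shape = lambda)
log_dinvgauss <- function(x, m, lambda) {
  0.5 * (log(lambda) - log(2 * pi) - 3 * log(x)) -
    lambda * (x - m)^2 / (2 * m^2 * x)
}

# event stdv of exactly 0 can arise from single-sample segmentation blocks;
# the IG density is undefined there, so clamp before evaluating
STDV_FLOOR <- 1e-3

#' Log emission probability of one event in one state
#'
#' The emission density is the product of the Gaussian density of the event
#' mean and the Inverse Gaussian density of the event standard deviation,
#' both under the scaled pore model.
#'
#' @param e list or one-row data.frame with fields `mean`, `stdv`, `start`.
#' @param k 0-based state index.
#' @inheritParams scaled_params
#' @return log density in nats.
#' @export
log_emission <- function(e, k, model, s = scaling_params()) {
  if (!all(is.finite(c(e$mean, e$stdv, e$start))))
    stop("event fields must be finite")
  p <- scaled_params(model, k, s, e$start)
  dnorm(e$mean, p$mean, p$sd, log = TRUE) +
    log_dinvgauss(max(e$stdv, STDV_FLOOR), p$ig_mean, p$ig_shape)
}

#' Log emission matrix for an event sequence
#'
#' Vectorized evaluation of [log_emission()] for every event against every
#' state; the workhorse feeding the forward-backward and Viterbi engines.
#'
#' @param events data.frame with columns `start`, `length`, `mean`, `stdv`.
#' @inheritParams scaled_params
#' @return numeric matrix, `nrow(events)` x `4^K`, of log densities.
#' @export
log_emission_matrix <- function(events, model, s = scaling_params()) {
  n <- nrow(events)
  S <- 4^model$K
  if (!all(is.finite(events$mean)) || !all(is.finite(events$stdv)))
    stop("event fields must be finite")
  gmu <- s$scale * model$level_mean + s$shift       # length S
  gsd <- s$var * model$level_stdv
  M <- outer(s$drift * events$start, gmu, "+")      # n x S scaled means
  G <- dnorm(events$mean, mean = M,
             sd = matrix(gsd, n, S, byrow = TRUE), log = TRUE)
  igm <- s$scale_sd * model$sd_mean
  igl <- s$var_sd * model$sd_stdv
  x <- pmax(events$stdv, STDV_FLOOR)
  IG <- 0.5 * (matrix(log(igl), n, S, byrow = TRUE) - log(2 * pi) -
                 3 * log(x)) -
    matrix(igl, n, S, byrow = TRUE) *
      (outer(x, igm, "-"))^2 / (2 * outer(x, igm^2))
  G + IG
}

#' Read / write a pore model table
#'
#' The on-disk format is a 5-column tab-separated table with header
#' `kmer level_mean level_stdv sd_mean sd_stdv`, one row per kmer; the kmer
#' length K is inferred from the kmer column and all `4^K` kmers must be
#' present exactly once. Write followed by read is the identity.
#'
#' @param path file path.
#' @param name model label; defaults to the file stem.
#' @return a [pore_model()].
#' @export
read_model_table <- function(path, name = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", rep("numeric", 4)),
                    stringsAsFactors = FALSE)
  need <- c("kmer", "level_mean", "level_stdv", "sd_mean", "sd_stdv")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("model table missing column(s): ", paste(miss, collapse = ", "))
  Ks <- unique(nchar(tab$kmer))
  if (length(Ks) != 1L) stop("inconsistent kmer lengths in model table")
  K <- Ks
  if (anyDuplicated(tab$kmer)) stop("duplicate kmer in model table")
  if (nrow(tab) != 4^K)
    stop("model table has ", nrow(tab), " rows; expected ", 4^K,
         " for K=", K, " (missing kmers)")
  idx <- kmer_index(tab$kmer)   # errors on non-ACGT
  ord <- order(idx)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  pore_model(tab$level_mean[ord], tab$level_stdv[ord],
             tab$sd_mean[ord], tab$sd_stdv[ord], name = name, K = K)
}

#' @rdname read_model_table
#' @param model a [pore_model()].
#' @export
write_model_table <- function(model, path) {
  tab <- data.frame(kmer = index_kmer(seq_len(4^model$K) - 1L, model$K),
                    level_mean = model$level_mean,
                    level_stdv = model$level_stdv,
                    sd_mean = model$sd_mean,
                    sd_stdv = model$sd_stdv)
  num <- vapply(tab[-1], function(col) sprintf("%.17g", col),
                character(nrow(tab)))
  write.table(cbind(kmer = tab$kmer, num),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
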