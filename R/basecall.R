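#' Convert a decoded state path to a DNA sequence
#'
#' Starting from the first state's kmer, each consecutive state pair
#' appends the minimum number of bases needed to realize the transition:
#' the smallest shift `s` in `0..K` with `suffix(prev, K-s) ==
#' prefix(next, K-s)` (so a stay appends nothing, and e.g. ACTCTC followed
#' by CTCTCA yields ACTCTCA). A direct consequence is that no basecalled
#' sequence can contain a homopolymer run longer than K.
#'
#' @param path integer vector of 0-based state indices (a `decoded_path`'s
#'   `path` element, or the object itself).
#' @param K kmer length.
#' @return DNA string.
#' @export
states_to_sequence <- function(path, K) {
  if (inherits(path, "decoded_path")) path <- path$path
  n <- length(path)
  if (n == 0L) stop("empty state path")
  if (n == 1L) return(index_kmer(path, K))
  prev <- path[-n]; nxt <- path[-1]
  shift <- rep(K, n - 1L)
  for (s in (K - 1L):0L) {     # smallest shift wins: scan downward
    match_s <- prev %% 4^(K - s) == nxt %/% 4^s
    shift[match_s] <- s
  }
  pieces <- character(n - 1L)
  nz <- shift > 0L
  if (any(nz)) {
    tails <- nxt[nz] %% 4^shift[nz]      # last `shift` bases of successor
    pieces[nz] <- vapply(seq_along(tails), function(i)
      index_kmer(tails[i], shift[nz][i]), "")
  }
  paste0(index_kmer(path[1], K), paste(pieces, collapse = ""))
}

#' Select the pore model for a strand
#'
#' If training already committed to a model (likelihood margin larger than
#' a factor of e^20 over every other candidate), that model wins
#' regardless of the Viterbi scores. Otherwise the candidate with the
#' highest joint log-probability of its most probable path is chosen, ties
#' going to the first model in load order.
#'
#' @param candidates list of per-model results, each with `model_name` and
#'   `logp` (Viterbi joint log-probability).
#' @param trained_selection model name fixed during training, or NA.
#' @return index of the chosen candidate.
#' @export
select_model <- function(candidates, trained_selection = NA_character_) {
  stopifnot(length(candidates) >= 1)
  names <- vapply(candidates, `[[`, "", "model_name")
  if (!is.na(trained_selection) && trained_selection %in% names)
    return(match(trained_selection, names))
  lp <- vapply(candidates, `[[`, numeric(1), "logp")
  which.max(lp)   # first maximum = first model in load order
}

# decode one strand with every applicable candidate and keep the winner
decode_strand <- function(events, candidates, trained_selection) {
  if (nrow(events) == 0L) return(NULL)
  events$start <- events$start - events$start[1]
  decoded <- lapply(candidates, function(cd) {
    tbl <- build_neighbour_table(cd$p_stay, cd$p_skip, cd$model$K)
    vit <- viterbi(events, cd$model, cd$params, tbl)
    list(model_name = cd$model$name, logp = vit$logp, path = vit$path,
         params = cd$params)
  })
  win <- decoded[[select_model(decoded, trained_selection)]]
  list(sequence = states_to_sequence(win$path, candidates[[1]]$model$K),
       model = win$model_name, logp = win$logp,
       n_events = nrow(events), params = win$params)
}

#' Basecall one read
#'
#' The full per-read pipeline: hairpin detection and strand separation,
#' per-strand scaling (and optional transition) training, Viterbi decoding
#' with every applicable pore model, model selection, and minimal-overlap
#' sequence reconstruction. Reads without a usable hairpin island are
#' basecalled entirely as a template strand. A failure in one strand does
#' not abort the other.
#'
#' @param events event data.frame (`start`, `length`, `mean`, `stdv`).
#' @param models list of [pore_model()]s (template + complement
#'   candidates), as in [train_read()].
#' @param config a [training_config()].
#' @param read_id read identifier used in FASTA headers.
#' @return list of class `basecall_result`: `read_id`, `split`, and
#'   per-strand entries `template` / `complement` (NULL when absent), each
#'   with `sequence`, `model`, `logp`, `n_events`, `params`.
#' @export
basecall_read <- function(events, models, config = training_config(),
                          read_id = "read") {
  stopifnot(nrow(events) >= 1)
  split <- split_read(events)
  training <- train_read(events, models, config, split = split)
  call_one <- function(range, candidates) {
    if (is.null(range) || is.null(candidates)) return(NULL)
    tryCatch(
      decode_strand(strand_events(events, range), candidates,
                    training$selected_complement),
      error = function(e) {
        warning("strand decoding failed: ", conditionMessage(e))
        NULL
      })
  }
  structure(list(read_id = read_id, split = split,
                 template = call_one(split$template_range,
                                     training$template),
                 complement = call_one(split$complement_range,
                                       training$complement),
                 training = training),
            class = "basecall_result")
}

#' @export
print.basecall_result <- function(x, ...) {
  cat(sprintf("basecall_result '%s':\n", x$read_id))
  for (strand in c("template", "complement")) {
    r <- x[[strand]]
    if (is.null(r)) next
    cat(sprintf("  %s: %d bases from %d events (model %s, logP %.1f)\n",
                strand, nchar(r$sequence), r$n_events, r$model, r$logp))
  }
  invisible(x)
}

#' Write basecall results as FASTA
#'
#' One record per decoded strand, headers `>{read_id}:{strand}` with the
#' chosen model as a comment field; sequence lines wrapped at 80 columns.
#' No quality values are produced (the per-base error rate makes them
#' uninformative), hence FASTA rather than FASTQ.
#'
#' @param results a `basecall_result` or list of them.
#' @param path output file path, or `""` for stdout.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(results, path = "") {
  if (inherits(results, "basecall_result")) results <- list(results)
  seqs <- character(0)
  for (res in results) {
    for (strand in c("template", "complement")) {
      r <- res[[strand]]
      if (is.null(r)) next
      nm <- sprintf("%s:%s model=%s", res$read_id, strand, r$model)
      seqs[nm] <- r$sequence
    }
  }
  if (!length(seqs)) {
    if (nzchar(path)) file.create(path)
    return(invisible(path))
  }
  dss <- Biostrings::DNAStringSet(seqs)
  if (nzchar(path)) {
    Biostrings::writeXStringSet(dss, path, width = 80L)
  } else {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    Biostrings::writeXStringSet(dss, tmp, width = 80L)
    writeLines(readLines(tmp))
  }
  invisible(path)
}
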