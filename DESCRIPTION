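Package: porecall
Title: Hidden Markov Model Basecalling for Nanopore Event Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An offline basecaller for segmented nanopore current events.
    Reads are split into template and complement strands by detecting the
    abasic hairpin signal, per-read pore-model scaling parameters are
    estimated by a Method-of-Moments initialization followed by
    Expectation-Maximization rounds driven by Forward-Backward posteriors,
    state-transition parameters are optionally refit by Baum-Welch, and the
    DNA sequence is decoded by Viterbi over a kmer-state hidden Markov
    model with a truncated sparse transition structure. Includes a
    generative event simulator so the whole pipeline can be exercised and
    validated against known ground truth without any instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
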