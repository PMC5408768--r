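test_that("state paths collapse to minimal-overlap sequences", {
  p <- kmer_index(c("ACTCTC", "CTCTCA"))
  expect_identical(states_to_sequence(p, 6), "ACTCTCA")
  # stays add nothing
  p2 <- kmer_index(c("AAAAAA", "AAAAAA", "AAAAAA"))
  expect_identical(states_to_sequence(p2, 6), "AAAAAA")
  # smallest shift 2 (one skip)
  p3 <- kmer_index(c("ACGTGT", "GTGTAC"))
  expect_identical(states_to_sequence(p3, 6), "ACGTGTAC")
  expect_identical(min_skips("ACGTGT", "GTGTAC"), 1L)
  # single state
  expect_identical(states_to_sequence(kmer_index("ACGT"), 4), "ACGT")
  # length bound: K + sum of shifts
  set.seed(61)
  tbl <- build_neighbour_table(.1, .3, 3)
  for (rep in 1:5) {
    path <- integer(20)
    path[1] <- sample(0:63, 1)
    for (t in 2:20) {
      nb <- tbl$nbr[path[t - 1] + 1, ]
      path[t] <- sample(nb[nb >= 0], 1)
    }
    s <- states_to_sequence(path, 3)
    expect_lte(nchar(s), 3 + 2 * 19)
    expect_gte(nchar(s), 3)
  }
})

test_that("model selection honours training then Viterbi score", {
  c1 <- list(model_name = "complement_1", logp = -1000)
  c2 <- list(model_name = "complement_2", logp = -990)
  expect_identical(select_model(list(c1)), 1L)
  expect_identical(select_model(list(c1, c2)), 2L)
  # a model fixed during training overrides a better Viterbi score
  expect_identical(select_model(list(c1, c2), "complement_1"), 1L)
  # tie goes to the first model in load order
  c3 <- list(model_name = "complement_2", logp = -1000)
  expect_identical(select_model(list(c1, c3)), 1L)
})

test_that("noise-free stay/skip-free reads decode exactly", {
  m <- seeded(62, simulate_pore_model(62, 4))
  tbl <- build_neighbour_table(0, 0, 4)
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, K = 4, seq_len = 150, p_stay = 0,
                      p_skip = 0, scaling = scaling_params(), noise = 0)
    sim <- seeded(seed, {
      sq <- random_dna_capped(150, 4)
      list(seq = sq, ev = simulate_events(sq, m, cfg))
    })
    expect_identical(nrow(sim$ev$events), 150L - 4L + 1L)
    vit <- viterbi(sim$ev$events, m, scaling_params(), tbl)
    expect_identical(vit$path, sim$ev$path)
    expect_identical(states_to_sequence(vit$path, 4), sim$seq)
  }
})

test_that("basecall_read produces both strands on a split read", {
  sim <- simulate_read(sim_config(seed = 63, noise = 0.25, p_skip = .05,
                                  scaling = scaling_params()))
  models <- list(sim$template_model, sim$complement_model)
  bc <- basecall_read(sim$events, models,
                      training_config(no_train = TRUE), "r63")
  expect_s3_class(bc, "basecall_result")
  expect_false(is.null(bc$template))
  expect_false(is.null(bc$complement))
  expect_gte(alignment_identity(bc$template$sequence,
                                sim$truth$template_seq), 0.9)
  expect_gte(alignment_identity(bc$complement$sequence,
                                sim$truth$complement_seq), 0.9)
  expect_lte(max_homopolymer(bc$template$sequence), 6)
  expect_lte(max_homopolymer(bc$complement$sequence), 6)
  expect_gte(nchar(bc$template$sequence), 6)
})

test_that("reads without a usable hairpin fall back to template-only", {
  # constant-level synthetic events: no island above threshold
  ev <- data.frame(start = seq(0, 6, length.out = 300), length = 0.02,
                   mean = seeded(64, runif(300, 60, 80)), stdv = 1.5)
  m <- seeded(65, simulate_pore_model(65, 2, name = "template"))
  bc <- basecall_read(ev, list(m), training_config(no_train = TRUE), "r")
  expect_null(bc$complement)
  expect_false(is.null(bc$template))
})

test_that("FASTA output has one wrapped record per decoded strand", {
  sim <- simulate_read(sim_config(seed = 66, noise = 0.25, p_skip = .05))
  models <- list(sim$template_model, sim$complement_model)
  bc <- basecall_read(sim$events, models,
                      training_config(no_train = TRUE), "readA")
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(bc, path)
  fa <- Biostrings::readDNAStringSet(path)
  expect_identical(length(fa), 2L)
  expect_true(all(grepl("^readA:(template|complement) model=",
                        names(fa))))
  expect_identical(as.character(fa[[1]]), bc$template$sequence)
  lines <- readLines(path)
  expect_lte(max(nchar(lines)), 80)
})
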