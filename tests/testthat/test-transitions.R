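test_that("untruncated transition rows sum to 1", {
  # exhaustive at K=2
  for (p in list(c(.1, .3), c(.25, .05))) {
    for (k1 in 0:15) {
      tot <- sum(vapply(0:15, function(k2)
        transition_prob_full(k1, k2, p[1], p[2], K = 2), 0))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
  # a few complete rows at K=6 (the 100-state sweep runs in the
  # acceptance suite)
  for (k1 in seeded(11, sample(0:4095, 5))) {
    tot <- sum(vapply(0:4095, function(k2)
      transition_prob_full(k1, k2, .1, .3, K = 6), 0))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("transition probability agrees with string-overlap oracle", {
  for (p_stay in c(.1, .2)) {
    for (k1 in 0:15) {
      for (k2 in 0:15) {
        s1 <- index_kmer(k1, 2); s2 <- index_kmer(k2, 2)
        expect_equal(transition_prob_full(s1, s2, p_stay, .3),
                     trans_full_bf(s1, s2, p_stay, .3),
                     tolerance = 1e-14)
      }
    }
  }
  # worked example: ACGTGT -> GTGTAC connects via shifts 2 and 4 only
  # (one or three skips), so tau = p_skip1/16 + p_skip1^3/256 + tail
  p_skip1 <- .3 / 1.3
  tail <- p_skip1^5 / ((1 - p_skip1) * 4^6)
  expect_equal(transition_prob_full("ACGTGT", "GTGTAC", .1, .3),
               p_skip1 / 16 + p_skip1^3 / 256 + tail, tolerance = 1e-14)
})

test_that("min_skips finds the smallest connecting shift", {
  expect_identical(min_skips("ACGTGT", "GTGTAC"), 1L)
  expect_identical(min_skips("ACGTAC", "CGTACA"), 0L)
  # exhaustive agreement with the brute-force overlap scanner at K=2
  for (k1 in 0:15) {
    for (k2 in 0:15) {
      s1 <- index_kmer(k1, 2); s2 <- index_kmer(k2, 2)
      expect_identical(min_skips(s1, s2), min_skips_bf(s1, s2))
    }
  }
})

test_that("truncated neighbour table has the documented sparse structure", {
  tbl <- build_neighbour_table(.1, .3, 6)
  counts <- as.integer(rowSums(tbl$nbr >= 0))
  expect_identical(max(counts), 21L)
  expect_true(all(counts <= 21L))
  # generic kmer: 21 distinct successors, 4 at shift 1 and 16 at shift 2
  g <- kmer_index("ACGTAC")
  expect_identical(counts[g + 1], 21L)
  nb <- tbl$nbr[g + 1, ]
  nb <- nb[nb >= 0]
  shifts <- vapply(nb, function(j)
    min_skips(index_kmer(g, 6), index_kmer(j, 6)) + 1L, 0L)
  shifts[nb == g] <- 0L
  expect_identical(sum(shifts == 1), 4L)
  expect_identical(sum(shifts == 2), 16L)
  # poly-A state: self and step successors coincide with skip successors
  expect_identical(counts[kmer_index("AAAAAA") + 1], 16L)
  # rows renormalized to 1
  expect_lt(max(abs(rowSums(exp(tbl$logp), na.rm = TRUE) - 1)), 1e-12)
})

test_that("truncation keeps a subset of the full support, mass-dominated", {
  tbl <- build_neighbour_table(.15, .2, 2)
  row_tot <- tbl$p_stay + tbl$p_step + tbl$p_skip1
  for (i in 1:16) {
    for (m in 1:21) {
      j <- tbl$nbr[i, m]
      if (j < 0) next
      full <- transition_prob_full(i - 1L, j, .15, .2, K = 2)
      kept <- exp(tbl$logp[i, m]) * row_tot  # pre-renormalization mass
      expect_gt(full, 0)
      expect_lte(kept, full + 1e-12)
    }
  }
})

test_that("Baum-Welch update inverts the renormalized class fractions", {
  # self-consistency: the updated parameters must reproduce the observed
  # shift-class fractions of the truncated (renormalized) chain
  for (masses in list(c(10, 60, 30), c(5, 80, 15), c(25, 70, 5))) {
    up <- update_transition_params(masses)
    Z <- up$p_stay + (1 - up$p_stay - up$p_skip) +
      up$p_skip / (1 + up$p_skip)
    expect_equal(up$p_stay / Z, masses[1] / sum(masses),
                 tolerance = 1e-12)
    expect_equal((up$p_skip / (1 + up$p_skip)) / Z,
                 masses[3] / sum(masses), tolerance = 1e-12)
  }
  # fixed point: class fractions of the true parameters map to themselves
  p <- c(.1, .3); p_skip1 <- .3 / 1.3
  Z <- .1 + .6 + p_skip1
  up <- update_transition_params(c(.1, .6, p_skip1) / Z)
  expect_equal(up$p_stay, .1, tolerance = 1e-12)
  expect_equal(up$p_skip, .3, tolerance = 1e-12)
  # degenerate masses clamp rather than collapse
  up2 <- update_transition_params(c(0, 100, 0))
  expect_equal(up2$p_stay, 1e-4)
  expect_equal(up2$p_skip, 1e-4)
  up3 <- update_transition_params(c(0, 0, 0),
                                  list(p_stay = .12, p_skip = .28))
  expect_equal(up3, list(p_stay = .12, p_skip = .28))
})

test_that("Baum-Welch recovers planted stay/skip rates from events", {
  # K=4 strand, >= 5000 events, planted p_stay=.1 / p_skip=.3
  model <- seeded(21, simulate_pore_model(21, 4))
  sim <- sim_strand(22, model, scaling_params(), n_bases = 6500,
                    p_stay = .1, p_skip = .3, noise = 0.5)
  expect_gte(nrow(sim$events), 5000)
  ps <- .2; pk <- .15        # start away from the truth
  for (r in 1:2) {
    tbl <- build_neighbour_table(ps, pk, 4)
    fb <- forward_backward(sim$events, model, scaling_params(), tbl)
    up <- update_transition_params(fb$shift_mass,
                                   list(p_stay = ps, p_skip = pk))
    ps <- up$p_stay; pk <- up$p_skip
  }
  expect_lt(abs(ps - .1), .05)
  expect_lt(abs(pk - .3), .05)
})
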