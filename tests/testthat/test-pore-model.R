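test_that("kmer indexing is the base-4 bijection", {
  expect_identical(kmer_index("AAAAAA"), 0L)
  expect_identical(kmer_index("TTTTTT"), 4095L)
  expect_identical(kmer_index("AAAAAC"), 1L)
  expect_error(kmer_index("ACGTXN"), "non-ACGT")
  for (K in c(2L, 4L, 6L)) {
    idx <- seeded(K, sample(0:(4^K - 1), min(50L, 4^K)))
    expect_identical(kmer_index(index_kmer(idx, K)), as.integer(idx))
  }
  # lexicographic order matches index order
  expect_identical(index_kmer(0:15, 2),
                   sort(index_kmer(0:15, 2)))
})

test_that("scaled_params applies the affine event-mean / IG scaling", {
  m <- seeded(1, simulate_pore_model(1, 3))
  neutral <- scaling_params()
  for (k in c(0L, 17L, 63L)) {
    p <- scaled_params(m, k, neutral, t = 0)
    expect_equal(p$mean, m$level_mean[k + 1])
    expect_equal(p$sd, m$level_stdv[k + 1])
    expect_equal(p$ig_mean, m$sd_mean[k + 1])
    expect_equal(p$ig_shape, m$sd_stdv[k + 1])
  }
  # additive shift
  s <- scaling_params(shift = 10)
  expect_equal(scaled_params(m, 5L, s)$mean, m$level_mean[6] + 10)
  # hand evaluation: 1.2*60 + 5 + 0.01*100 = 78
  m2 <- pore_model(level_mean = rep(60, 16), level_stdv = rep(1, 16),
                   sd_mean = rep(1, 16), sd_stdv = rep(1, 16), K = 2)
  s2 <- scaling_params(shift = 5, scale = 1.2, drift = 0.01)
  expect_equal(scaled_params(m2, 0L, s2, t = 100)$mean, 78)
})

test_that("log emission is the Gaussian x Inverse-Gaussian log density", {
  m <- pore_model(level_mean = seq(51, 81, by = 2), level_stdv = rep(1, 16),
                  sd_mean = rep(2, 16), sd_stdv = rep(5, 16), K = 2)
  # Gaussian part at its mode with sd = 1 contributes -log(sqrt(2*pi));
  # IG part at x = ig mean contributes 0.5*log(lambda/(2 pi m^3))
  e <- list(start = 0, length = 0.01, mean = 51, stdv = 2)
  expected <- -0.5 * log(2 * pi) + 0.5 * log(5 / (2 * pi * 2^3))
  expect_equal(log_emission(e, 0L, m), expected, tolerance = 1e-12)
  expect_equal(-0.5 * log(2 * pi), -0.9189, tolerance = 1e-4)

  # doubling the Gaussian sd strictly lowers the mode density
  m2 <- m; m2$level_stdv <- rep(2, 16)
  expect_lt(log_emission(e, 0L, m2), log_emission(e, 0L, m))

  # matrix evaluation agrees with the scalar one under arbitrary scaling
  ev <- data.frame(start = c(0, 0.5), length = 0.02,
                   mean = c(55, 70), stdv = c(1.4, 2.6))
  s <- scaling_params(shift = 3, scale = 1.1, drift = 0.2, var = 1.3,
                      scale_sd = 0.9, var_sd = 1.4)
  le <- log_emission_matrix(ev, m, s)
  for (i in 1:2) {
    for (k in c(0L, 7L, 15L)) {
      expect_equal(le[i, k + 1], log_emission(ev[i, ], k, m, s),
                   tolerance = 1e-12)
    }
  }
  expect_error(log_emission(list(start = 0, mean = NaN, stdv = 1), 0L, m),
               "finite")
})

test_that("both emission factors integrate to 1 over their observable", {
  m <- seeded(4, simulate_pore_model(4, 2))
  s <- scaling_params(shift = 2, scale = 1.05, drift = 0.1, var = 1.2,
                      scale_sd = 1.1, var_sd = 0.8)
  p <- scaled_params(m, 9L, s, t = 3)
  gauss <- integrate(function(x) dnorm(x, p$mean, p$sd),
                     p$mean - 12 * p$sd, p$mean + 12 * p$sd,
                     rel.tol = 1e-10)
  expect_equal(gauss$value, 1, tolerance = 1e-6)
  ig <- integrate(function(x)
    exp(0.5 * (log(p$ig_shape) - log(2 * pi) - 3 * log(x)) -
          p$ig_shape * (x - p$ig_mean)^2 / (2 * p$ig_mean^2 * x)),
    1e-8, Inf, rel.tol = 1e-10)
  expect_equal(ig$value, 1, tolerance = 1e-6)
})

test_that("model tables round-trip and reject malformed input", {
  m <- seeded(7, simulate_pore_model(7, 2, name = "tpl"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model_table(m, path)
  m2 <- read_model_table(path, name = "tpl")
  expect_equal(m2[c("level_mean", "level_stdv", "sd_mean", "sd_stdv")],
               m[c("level_mean", "level_stdv", "sd_mean", "sd_stdv")])
  expect_identical(m2$K, 2L)

  # missing kmer
  tab <- read.table(path, header = TRUE, sep = "\t")
  write.table(tab[-5, ], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_model_table(path), "missing kmers")

  # bad alphabet
  tab2 <- tab; tab2$kmer[1] <- "AX"
  write.table(tab2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_model_table(path), "non-ACGT")

  # duplicate kmer
  tab3 <- tab; tab3$kmer[2] <- tab3$kmer[1]
  write.table(tab3, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_model_table(path), "duplicate")

  # non-positive spread parameters rejected at construction
  expect_error(pore_model(rep(60, 16), rep(0, 16), rep(1, 16),
                          rep(1, 16), K = 2), "strictly positive")
})
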