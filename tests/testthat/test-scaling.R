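test_that("Method of Moments matches level moments exactly", {
  m <- seeded(31, simulate_pore_model(31, 3))
  # events whose means are exactly the model levels -> neutral
  ev <- data.frame(start = seq(0, 1, length.out = 64), length = 0.02,
                   mean = m$level_mean, stdv = 2)
  p <- mom_init(ev, m)
  expect_equal(p$scale, 1, tolerance = 1e-9)
  expect_equal(p$shift, 0, tolerance = 1e-9)
  expect_equal(p$drift, 0)
  expect_equal(p$var, 1)
  # affine-transformed events recover (scale, shift)
  ev2 <- ev; ev2$mean <- 1.2 * ev$mean + 10
  p2 <- mom_init(ev2, m)
  expect_equal(p2$scale, 1.2, tolerance = 1e-6)
  expect_equal(p2$shift, 10, tolerance = 1e-6)
  # order invariance
  p3 <- mom_init(ev2[seeded(5, sample(64)), ], m)
  expect_equal(p3$scale, p2$scale)
  expect_equal(p3$shift, p2$shift)
  # degenerate: constant means
  ev4 <- ev; ev4$mean <- 70
  p4 <- mom_init(ev4, m)
  expect_equal(p4$scale, 1)
  expect_equal(p4$shift, 70 - mean(m$level_mean))
})

test_that("one EM round is a near fixed point at the truth", {
  m <- seeded(32, simulate_pore_model(32, 4))
  sim <- sim_strand(33, m, scaling_params(), n_bases = 210,
                    p_stay = .1, p_skip = .05, noise = 0.5)
  ev <- sim$events[1:200, ]
  tbl <- build_neighbour_table(.1, .3, 4)
  em <- em_round(ev, m, tbl, scaling_params())
  expect_lt(abs(em$params$shift), 0.5)
  expect_lt(abs(em$params$scale - 1), 0.05)
  expect_lt(abs(em$params$drift), 0.05)
})

test_that("EM increases the likelihood monotonically", {
  m <- seeded(34, simulate_pore_model(34, 4))
  true <- scaling_params(shift = 6, scale = 1.08, drift = 0.05,
                         var = 0.8, scale_sd = 1.1, var_sd = 1.2)
  sim <- sim_strand(35, m, true, n_bases = 260, noise = 1)
  chains <- list(sim$events[1:120, ], sim$events[130:250, ])
  tbl <- build_neighbour_table(.1, .3, 4)
  params <- mom_init(do.call(rbind, chains), m)
  liks <- numeric(8)
  for (r in 1:8) {
    em <- em_round(chains, m, tbl, params)
    liks[r] <- em$loglik
    params <- em$params
  }
  expect_true(all(diff(liks) > -1e-6))
})

test_that("EM recovers planted scaling from a seeded strand", {
  m <- seeded(36, simulate_pore_model(36, 4))
  true <- scaling_params(shift = 8, scale = 1.1, drift = 0.02,
                         var = 1.5, scale_sd = 1.05, var_sd = 1.2)
  sim <- sim_strand(37, m, true, n_bases = 1100, noise = 1)
  chains <- porecall:::training_chains(sim$events, 100)
  params <- porecall:::init_drift(mom_init(sim$events, m), chains)
  tbl <- build_neighbour_table(.1, .3, 4)
  for (r in 1:10) params <- em_round(chains, m, tbl, params)$params
  expect_lt(abs(params$shift - 8) / 8, 0.10)
  expect_lt(abs(params$scale - 1.1) / 1.1, 0.10)
  # a 0.02 pA/s drift is near the moment-contrast noise floor at n=200,
  # so the bound is absolute; relative recovery is tested at drift=0.1
  expect_lt(abs(params$drift - 0.02), 0.02)
  expect_lt(abs(params$var - 1.5) / 1.5, 0.15)
  expect_lt(abs(params$scale_sd - 1.05) / 1.05, 0.10)
})

test_that("no_train returns the Method-of-Moments parameters exactly", {
  sim <- simulate_read(sim_config(seed = 41))
  sp <- split_read(sim$events)
  models <- list(sim$template_model, sim$complement_model)
  tr <- train_read(sim$events, models,
                   training_config(no_train = TRUE), split = sp)
  tev <- sim$events[sp$template_range[1]:(sp$template_range[2] - 1), ]
  expect_equal(tr$template[[1]]$params, mom_init(tev, sim$template_model))
  expect_identical(tr$template[[1]]$rounds, 0L)
})

test_that("double-strand mode shares one parameter set across strands", {
  sim <- simulate_read(sim_config(seed = 42, noise = 0.5, p_skip = .05))
  models <- list(sim$template_model, sim$complement_model)
  sp <- split_read(sim$events)
  tr2 <- train_read(sim$events, models,
                    training_config(mode = "double_strand"), split = sp)
  # shared estimate: bitwise-identical parameters for both strands
  expect_identical(tr2$template[[1]]$params, tr2$complement[[1]]$params)

  tr1 <- train_read(sim$events, models,
                    training_config(mode = "single_strand"), split = sp)
  p_t <- unlist(tr1$template[[1]]$params)
  p_c <- unlist(tr1$complement[[1]]$params)
  # independent training gives strictly different per-strand estimates
  expect_gt(max(abs(p_t - p_c)), 0)
})

test_that("a 20-nat likelihood margin selects the complement model", {
  sim <- simulate_read(sim_config(seed = 43, noise = 0.5, p_skip = .05))
  decoy <- simulate_pore_model(999, 6, name = "complement_2")
  models <- list(sim$template_model, sim$complement_model, decoy)
  tr <- train_read(sim$events, models, training_config(), split = NULL)
  expect_identical(tr$selected_complement, "complement_1")
  lik <- vapply(tr$complement, `[[`, 0, "loglik")
  expect_gt(abs(diff(lik)), 20)
})

test_that("empty strands degrade gracefully", {
  ev <- data.frame(start = seq(0, 2, length.out = 200), length = 0.01,
                   mean = rep(70, 200), stdv = 1.5)
  # whole-read template, no complement: trains without warning
  expect_no_warning(
    tr <- train_read(ev[1:3, ],
                     list(seeded(2, simulate_pore_model(2, 2))),
                     training_config(no_train = TRUE)))
  expect_null(tr$complement)
})
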