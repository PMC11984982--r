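test_that("observation sets validate their records", {
  po <- data.frame(day = c(0, 7), count = c(100, 50))
  ao <- data.frame(kind = c("interval_cumulative", "single_day"),
                   start = c(1, 21), end = c(126, 21), count = c(870, 150))
  obs <- observation_set(po, ao)
  expect_s3_class(obs, "observation_set")
  expect_error(observation_set(po[0, ], ao), "at least one")
  expect_error(observation_set(data.frame(day = -1, count = 5)),
               "non-negative")
  bad <- ao; bad$kind[1] <- "weekly"
  expect_error(observation_set(po, bad), "kind")
  bad2 <- ao; bad2$end[2] <- 22
  expect_error(observation_set(po, bad2), "start == end")
})

test_that("predictions align with observations and are self-consistent", {
  ds <- yvm_fixture()  # sigma = 0
  init <- ref_init()
  pred <- predict_observables(reference_params(), init, ds$obs)
  obs_pa <- ds$obs$participant_obs$count
  # counts are rounded to whole persons; allow the 0.5-person slack on top of
  # solver accuracy
  expect_true(all(abs(pred$participants - obs_pa) <=
                    0.5 + 1e-6 * pmax(obs_pa, 1)))
  expect_true(all(abs(pred$arrests - ds$obs$arrest_obs$count) <= 0.5 + 1e-4))
  # day-0 record equals the initial condition
  expect_equal(pred$participants[1], 288000, tolerance = 1e-9)
  # without any policing all predicted arrests vanish
  pred0 <- predict_observables(no_policing(reference_params()), init, ds$obs)
  expect_equal(pred0$arrests, rep(0, 3))
})

test_that("misfit implements weighted relative least squares", {
  p <- decay_params(delta1 = 0.1)
  init <- initial_state(1e6, 1e5)
  # single participant record with a known prediction: I(10) = 1e5 e^{-1}
  pred10 <- 1e5 * exp(-1)
  obs <- observation_set(data.frame(day = 10, count = 100))
  expect_equal(misfit(p, init, obs, weights = c(1, 0)),
               ((pred10 - 100) / 100)^2, tolerance = 1e-6)
  # hand example: obs 100, pred 110 -> (10/100)^2
  obs2 <- observation_set(data.frame(day = 10, count = pred10 / 1.1))
  expect_equal(misfit(p, init, obs2, weights = c(1, 0)), 0.01,
               tolerance = 1e-4)
  # linear in the weights
  obs3 <- yvm_fixture(seed = 2, noise_sigma = 0.2)$obs
  m1 <- misfit(reference_params(), ref_init(), obs3, weights = c(1, 1))
  m2 <- misfit(reference_params(), ref_init(), obs3, weights = c(2, 2))
  expect_equal(m2, 2 * m1, tolerance = 1e-12)
  expect_error(misfit(p, init, obs, weights = c(0, 0)), "not both zero")
  # perfect predictions give zero
  obs4 <- observation_set(data.frame(day = 10, count = pred10))
  expect_lt(misfit(p, init, obs4, weights = c(1, 0)), 1e-10)
})

test_that("misfit at the generating truth on a noise-free fixture is tiny", {
  ds <- yvm_fixture(noise_sigma = 0)
  # rounding to whole persons leaves a floor; with unrounded observations the
  # generator/predictor self-consistency is at solver level
  ds_exact <- generate_observations(reference_params(), ref_init(),
                                    seq(0, 224, 7), noise_sigma = 0,
                                    round_counts = FALSE)
  expect_lt(misfit(reference_params(), ref_init(), ds_exact$obs,
                   rtol = 1e-10, atol = 1e-6), 1e-10)
  expect_lt(misfit(reference_params(), ref_init(), ds$obs), 1e-5)
})

test_that("fit configuration validates bounds and masks", {
  p <- reference_params()
  cfg <- fit_config(p)
  expect_setequal(cfg$free, c("beta1", "beta2", "chi", "n", "c0",
                              "delta1", "delta2"))
  expect_true(all(cfg$lower <= param_values_for_test(p, cfg$free)))
  expect_error(fit_config(p, lower = c(beta1 = 1), upper = c(beta1 = 0.1)),
               "bounds")
  cfg2 <- fit_config(p, free = c("beta1", "eps12"))
  expect_equal(unname(cfg2$lower[["eps12"]]), 0.015)
})

test_that("fixed-parameter fits and determinism behave as contracted", {
  ds <- generate_observations(reference_params(), ref_init(),
                              seq(0, 63, 7), noise_sigma = 0.05, seed = 4)
  init <- ref_init()
  # all parameters fixed: objective equals the template misfit
  cfg0 <- fit_config(reference_params(), free = character(0))
  fr0 <- fit_protests(ds$obs, init, cfg0)
  expect_equal(fr0$objective,
               misfit(reference_params(), init, ds$obs, rtol = cfg0$rtol,
                      atol = cfg0$atol))
  expect_true(fr0$converged)

  # same seed twice: bit-identical results
  cfg <- fit_config(reference_params(), free = c("beta1", "delta1"),
                    n_starts = 8, maxit = 15, global_rounds = 1,
                    cascade_cycles = 2, seed = 7, ftol = 1e-30)
  fr1 <- fit_protests(ds$obs, init, cfg)
  fr2 <- fit_protests(ds$obs, init, cfg)
  expect_identical(fr1$par, fr2$par)
  expect_identical(fr1$objective, fr2$objective)
  # the reported objective is the best of all polish stages
  expect_equal(fr1$objective, min(fr1$start_objectives))
})

test_that("a truncated-data (training-set) fit predicts the held-out weeks", {
  ds <- yvm_fixture(seed = 5, noise_sigma = 0.05)
  init <- ref_init()
  obs_train <- truncate_observations(ds$obs, 126)
  expect_true(all(obs_train$participant_obs$day <= 126))
  expect_true(all(obs_train$arrest_obs$end <= 126))

  truth <- reference_params()
  free <- c("beta1", "beta2", "chi", "delta1", "delta2")
  tv <- param_values_for_test(truth, free)
  tmpl <- perturbed_template(truth, free, amp = 0.25, seed = 31)
  cfg <- fit_config(tmpl, free = free, lower = tv / 10, upper = tv * 10,
                    global_rounds = 0, cascade_cycles = 6, seed = 5)
  fr <- fit_protests(obs_train, init, cfg)

  hold_days <- ds$obs$participant_obs$day[ds$obs$participant_obs$day > 126]
  tr_hat <- simulate_protests(fr$q_hat, init, 260)
  tr_true <- simulate_protests(truth, init, 260)
  pred <- participants(tr_hat, hold_days)
  held <- participants(tr_true, hold_days)
  expect_gt(cor(pred, held), 0)
})
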