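test_that("withdrawal rate has the Hill limits and monotone shape", {
  p <- small_params(delta1 = 0.4, delta2 = 0.02, c0 = 2e4, n = 2)
  expect_equal(withdrawal_rate(0, p), 0.4)
  expect_equal(withdrawal_rate(2e4, p), (0.4 + 0.02) / 2)
  expect_equal(withdrawal_rate(1e6 * 2e4, p), 0.02, tolerance = 1e-9)
  # monotone non-increasing, bounded in [delta2, delta1]
  N <- 10^seq(0, 7, length.out = 60)
  w <- withdrawal_rate(N, p)
  expect_true(all(diff(w) <= 0))
  expect_true(all(w >= 0.02 & w <= 0.4))
  # no collective effect when delta1 == delta2
  pflat <- small_params(delta1 = 0.1, delta2 = 0.1)
  expect_equal(withdrawal_rate(N, pflat), rep(0.1, length(N)))
  expect_error(withdrawal_rate(-1, p), "N must be")
})

test_that("policing schedule evaluates right-continuously with half-open intervals", {
  sched <- policing_two_phase(0.01, 0.02, 0.5, 0.6, windows = list(c(20, 21)))
  expect_equal(unname(policing_at(10, sched)), matrix(c(0.01, 0.02), 1))
  expect_equal(unname(policing_at(20.5, sched)), matrix(c(0.5, 0.6), 1))
  # boundary convention: strong pair from t = 20, weak again at t = 21
  expect_equal(policing_at(20, sched)[, "eps1"], c(eps1 = 0.5))
  expect_equal(policing_at(21, sched)[, "eps2"], c(eps2 = 0.02))
  # constant extrapolation beyond last breakpoint
  expect_equal(policing_at(1e4, sched)[, "eps1"], c(eps1 = 0.01))
  single <- policing_schedule(numeric(0), 0.3, 0.4)
  expect_equal(policing_at(c(0, 5, 500), single)[, "eps1"],
               rep(0.3, 3), ignore_attr = TRUE)
  expect_error(policing_schedule(c(5, 5), c(1, 1, 1), c(1, 1, 1)),
               "strictly increasing")
  expect_error(policing_schedule(5, c(1, -1), c(1, 1)), "non-negative")
})

test_that("parameter validation enforces the model's invariants", {
  expect_error(small_params(delta1 = 0.1, delta2 = 0.2), "delta1")
  expect_error(small_params(beta1 = -1), "non-negative")
  expect_error(small_params(c0 = 0), "positive")
  expect_error(small_params(n = 0), "positive")
})

test_that("rhs reproduces hand-computed derivatives and conserves the population", {
  # protest-free equilibrium: everything zero
  p <- small_params()
  x0 <- c(S = 1e6, I = 0, C = 0, R = 0, D = 0, A = 0)
  expect_equal(protest_rhs(0, x0, p), c(S = 0, I = 0, C = 0, R = 0, D = 0, A = 0))

  # direct substitution: only mass-action recruitment active
  p2 <- protest_params(beta1 = 0.01, beta2 = 0, gamma = 0, chi = 0,
                       delta1 = 0, delta2 = 0, c0 = 10, n = 1, eps3 = 0,
                       policing = policing_schedule())
  d2 <- protest_rhs(0, c(S = 100, I = 10, C = 0, R = 0, D = 0, A = 0), p2)
  expect_equal(unname(d2), c(-10, 10, 0, 0, 0, 0))

  # conservation identity on random states/parameters
  set.seed(42)
  for (i in 1:25) {
    p3 <- small_params(beta1 = 10^runif(1, -10, -7), chi = runif(1),
                       delta1 = runif(1, 0.5, 1), delta2 = runif(1, 0, 0.4),
                       eps3 = runif(1))
    x <- setNames(c(runif(5, 0, 1e6), 0), c("S", "I", "C", "R", "D", "A"))
    dx <- protest_rhs(runif(1, 0, 100), x, p3)
    expect_equal(sum(dx[c("S", "I", "C", "R", "D")]), 0, tolerance = 1e-9)
  }
  expect_error(protest_rhs(0, c(S = -1, I = 0, C = 0, R = 0, D = 0, A = 0), p),
               "non-negative")
})

test_that("initial state construction matches the aggregate population split", {
  s <- initial_state(55.5e6, 288000)
  expect_equal(unname(s), c(55212000, 288000, 0, 0, 0, 0))
  expect_equal(unname(initial_state(100, 0)), c(100, 0, 0, 0, 0, 0))
  expect_error(initial_state(10, 11), "exceed")
  s2 <- initial_state(1000, 100, c0_init = 50)
  expect_equal(s2[["S"]], 850)
  expect_equal(s2[["C"]], 50)
})

test_that("parameters round-trip through the JSON config", {
  p <- small_params()
  path <- withr::local_tempfile(fileext = ".json")
  write_params(p, path)
  p2 <- read_params(path)
  nm <- c("beta1", "beta2", "gamma", "chi", "delta1", "delta2", "c0", "n",
          "eps3")
  expect_equal(p2[nm], p[nm])
  expect_equal(p2$policing$breaks, p$policing$breaks)
  expect_equal(p2$policing$eps1, p$policing$eps1)
  expect_equal(p2$policing$phases$weak, p$policing$phases$weak)
  # general (non-two-phase) schedule round-trips too
  p3 <- small_params(policing = policing_schedule(c(5, 30), c(0, 1, 2) / 100,
                                                  c(3, 4, 5) / 100))
  path3 <- withr::local_tempfile(fileext = ".json")
  write_params(p3, path3)
  p4 <- read_params(path3)
  expect_equal(p4$policing$breaks, c(5, 30))
  expect_equal(p4$policing$eps2, c(0.03, 0.04, 0.05))
})
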