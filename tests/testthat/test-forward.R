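test_that("closed-form trajectories are reproduced", {
  # all rates zero: constant state
  p0 <- decay_params(delta1 = 0, delta2 = 0)
  init <- c(S = 1e5, I = 5e3, C = 2e3, R = 0, D = 0, A = 0)
  tr0 <- simulate_protests(p0, init, 50)
  expect_true(all(abs(t(tr0$states) - unname(init)) < 1e-6))

  # pure exponential decay of novices: I(t) = I0 exp(-delta1 t)
  p <- decay_params(delta1 = 0.3)
  init <- initial_state(1e6, 1e5)
  tr <- simulate_protests(p, init, 40)
  expect_equal(tr$states[, "I"], 1e5 * exp(-0.3 * tr$times),
               tolerance = 1e-6)
  expect_equal(participants(tr, c(0, 10, 25)), 1e5 * exp(-0.3 * c(0, 10, 25)),
               tolerance = 1e-6)
})

test_that("trajectory invariants hold: conservation, monotone arrests, span checks", {
  p <- small_params()
  init <- ref_init()
  tr <- simulate_protests(p, init, 260)
  tot <- rowSums(tr$states[, c("S", "I", "C", "R", "D")])
  expect_true(max(abs(tot - sum(init[1:5])) / sum(init[1:5])) <= 1e-6)
  expect_true(all(diff(tr$states[, "A"]) >= -1e-6))
  expect_true(all(tr$states >= 0))
  expect_error(participants(tr, 300), "outside")
  expect_error(simulate_protests(p, init, -5), "positive")
  expect_error(simulate_protests(p, init, 10, output_times = c(0, 20)),
               "output_times")
})

test_that("solver is converged and breakpoint restarts are inert", {
  p <- small_params()
  init <- ref_init()
  days <- seq(0, 200, by = 5)
  tr1 <- simulate_protests(p, init, 200, output_times = days)
  tr2 <- simulate_protests(p, init, 200, output_times = days,
                           rtol = 1e-9, atol = 1e-5)
  pa1 <- participants(tr1)
  pa2 <- participants(tr2)
  expect_true(max(abs(pa1 - pa2) / pmax(pa2, 1)) < 1e-4)

  # a redundant breakpoint (same rates on both sides) must not change anything
  pc <- small_params(policing = policing_schedule(numeric(0), 0.01, 0.02))
  pb <- small_params(policing = policing_schedule(100, c(0.01, 0.01),
                                                  c(0.02, 0.02)))
  ta <- simulate_protests(pc, init, 200, output_times = days)
  tb <- simulate_protests(pb, init, 200, output_times = days)
  expect_equal(participants(ta), participants(tb), tolerance = 1e-6)
})

test_that("cumulative arrests match independent quadrature of the detention flux", {
  p <- small_params()
  init <- ref_init()
  grid <- seq(0, 100, by = 0.05)
  tr <- simulate_protests(p, init, 100, output_times = grid)
  # piecewise Simpson between schedule breakpoints (flux jumps at 20 and 21;
  # within each segment the rates are the constant pair of that interval)
  segs <- list(c(0, 20), c(20, 21), c(21, 100))
  A_quad <- sum(vapply(segs, function(s) {
    i <- which(grid >= s[1] - 1e-9 & grid <= s[2] + 1e-9)
    eps <- policing_at(mean(s), p$policing)
    flux <- eps[, "eps1"] * tr$states[i, "I"] + eps[, "eps2"] * tr$states[i, "C"]
    simpson(grid[i], flux)
  }, numeric(1)))
  A_sol <- unname(tr$states[length(grid), "A"])
  expect_equal(A_quad, A_sol, tolerance = 1e-5)

  expect_equal(arrests_in_window(tr, 40, 40), 0)
  expect_error(arrests_in_window(tr, 50, 40), "a <= b")
  pz <- small_params(policing = policing_schedule())
  trz <- simulate_protests(pz, init, 50)
  expect_equal(arrests_in_window(trz, 0, 50), 0)
})

test_that("arrest windows integrate a frozen detention flux exactly", {
  # beta = chi = 0 and delta1 = 0 freeze I; arrests then grow linearly
  p <- protest_params(0, 0, 0, 0, 0, 0, 1e4, 2, 0,
                      policing = policing_schedule(numeric(0), 0.02, 0))
  init <- c(S = 0, I = 1000, C = 0, R = 0, D = 0, A = 0)
  # detention does remove people from I, so use the exact closed form:
  # I(t) = I0 e^{-eps1 t}, A(a,b) = I0 (e^{-eps1 a} - e^{-eps1 b})
  tr <- simulate_protests(p, init, 30)
  expect_equal(arrests_in_window(tr, 5, 12),
               1000 * (exp(-0.02 * 5) - exp(-0.02 * 12)), tolerance = 1e-7)
})

test_that("protest duration reads the grid per its definition", {
  p <- decay_params(delta1 = 0.2)
  init <- initial_state(1e6, 1e5)
  tr <- simulate_protests(p, init, 80)
  # closed form: crosses h at t = ln(I0/h)/delta1
  h <- 500
  expect_lte(abs(protest_duration(tr, h) - log(1e5 / h) / 0.2), 1)
  # identically below threshold
  expect_equal(protest_duration(tr, 2e5), 0)
  # never below threshold: returns the span
  expect_equal(protest_duration(tr, 1e-3), 80)
  expect_error(protest_duration(tr, 0), "positive")
})

test_that("trajectory CSV export has the documented columns and values", {
  p <- small_params()
  tr <- simulate_protests(p, ref_init(), 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  df <- read.csv(path)
  expect_identical(names(df),
                   c("time", "S", "I", "C", "R", "D", "A", "participants"))
  expect_equal(df$participants, unname(participants(tr)), tolerance = 1e-12)
})
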