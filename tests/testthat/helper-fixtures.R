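# Small parameter sets and independent numerical oracles used across tests.

# generic small parameter set with a day 20-21 active policing phase
small_params <- function(...) {
  args <- list(beta1 = 1e-8, beta2 = 1e-9, gamma = 0.002, chi = 0.05,
               delta1 = 0.4, delta2 = 0.02, c0 = 2e4, n = 2, eps3 = 0.1,
               policing = policing_two_phase(0.001, 0.002, 0.1, 0.2))
  do.call(protest_params, utils::modifyList(args, list(...)))
}

# parameters with every rate zero except those supplied
decay_params <- function(delta1 = 0.3, delta2 = 0) {
  protest_params(beta1 = 0, beta2 = 0, gamma = 0, chi = 0,
                 delta1 = delta1, delta2 = delta2, c0 = 1e4, n = 2,
                 eps3 = 0, policing = policing_schedule())
}

# independent fixed-step classical RK4 for the 4-equation baseline model
# (no detention): S, I, C, R only
rk4_baseline <- function(p, init, t_end, h = 0.01, out_times) {
  y <- init[c("S", "I", "C", "R")]
  rhs4 <- function(y) {
    w <- p$delta2 + (p$delta1 - p$delta2) * p$c0^p$n /
      ((y[2] + y[3])^p$n + p$c0^p$n)
    rec <- p$beta1 * y[1] * y[2] + p$beta2 * y[1] * y[3]
    c(-rec + p$gamma * y[4],
      rec - (p$chi + p$delta1) * y[2],
      p$chi * y[2] - w * y[3],
      p$delta1 * y[2] + w * y[3] - p$gamma * y[4])
  }
  nstep <- ceiling(t_end / h)
  h <- t_end / nstep
  times <- numeric(0)
  out <- NULL
  grid <- seq(0, t_end, by = h)
  want <- vapply(out_times, function(t) which.min(abs(grid - t)), integer(1))
  store <- matrix(NA_real_, length(out_times), 4)
  if (1 %in% want) store[want == 1, ] <- rep(y, each = sum(want == 1))
  for (i in seq_len(nstep)) {
    k1 <- rhs4(y)
    k2 <- rhs4(y + h / 2 * k1)
    k3 <- rhs4(y + h / 2 * k2)
    k4 <- rhs4(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    hit <- which(want == i + 1)
    if (length(hit)) store[hit, ] <- rep(y, each = length(hit))
  }
  colnames(store) <- c("S", "I", "C", "R")
  store
}

# composite Simpson quadrature on an evenly spaced grid (odd number of points)
simpson <- function(x, y) {
  n <- length(x)
  stopifnot(n %% 2 == 1)
  h <- x[2] - x[1]
  h / 3 * (y[1] + y[n] + 4 * sum(y[seq(2, n - 1, by = 2)]) +
             2 * sum(y[seq(3, n - 2, by = 2)]))
}

# reference initial condition used throughout (55.5M adults, 288k first-day
# protesters)
ref_init <- function() initial_state(55.5e6, 288000)

# named parameter values, including two-phase schedule entries
param_values_for_test <- function(p, names) {
  protestdyn:::param_values(p, names)
}

# perturb the free parameters of a template multiplicatively (log-uniform)
perturbed_template <- function(p, free, amp, seed) {
  tv <- param_values_for_test(p, free)
  set.seed(seed)
  protestdyn:::param_update(p, as.list(tv * exp(runif(length(free),
                                                      -amp, amp))))
}
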