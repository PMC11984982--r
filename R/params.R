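#' @useDynLib protestdyn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx optim runif rnorm setNames
#' @importFrom utils read.csv write.csv
NULL

PAR_NAMES <- c("beta1", "beta2", "gamma", "chi", "delta1", "delta2",
               "c0", "n", "eps3")

#' Piecewise-constant policing schedule
#'
#' Detention rates for novice (`eps1`) and experienced (`eps2`) protesters as
#' right-continuous step functions of time. With `k` breakpoints there are
#' `k + 1` intervals (before the first breakpoint, between consecutive ones,
#' and after the last); the value on `[t_k, t_{k+1})` is the pair of that
#' interval.
#'
#' @param breaks strictly increasing breakpoint times in days (may be empty).
#' @param eps1,eps2 per-interval detention rates (per day), length
#'   `length(breaks) + 1`.
#' @return an object of class `policing_schedule`.
#' @seealso [policing_two_phase()] for the weak-phase/active-phase special
#'   case used throughout the protest analyses.
#' @export
policing_schedule <- function(breaks = numeric(0),
                              eps1 = 0, eps2 = 0) {
  breaks <- as.numeric(breaks)
  eps1 <- as.numeric(eps1)
  eps2 <- as.numeric(eps2)
  if (length(breaks) && any(diff(breaks) <= 0))
    stop("schedule breakpoints must be strictly increasing")
  if (length(eps1) != length(breaks) + 1 ||
      length(eps2) != length(breaks) + 1)
    stop("need one (eps1, eps2) pair per interval: length(breaks) + 1 values")
  if (any(!is.finite(c(breaks, eps1, eps2))) || any(c(eps1, eps2) < 0))
    stop("detention rates must be finite and non-negative")
  structure(list(breaks = breaks, eps1 = eps1, eps2 = eps2, phases = NULL),
            class = "policing_schedule")
}

#' Two-phase policing schedule (weak phase plus short active windows)
#'
#' Builds the schedule used in the case study: low "weak-phase" detention
#' rates everywhere except one or more short "active" windows where the police
#' acts harder (`eps12 > eps11`, `eps22 > eps21`). The default single active
#' window is day 20 to 21 (half-open `[20, 21)`).
#'
#' @param eps11,eps21 weak-phase detention rates for novice / experienced
#'   protesters (per day).
#' @param eps12,eps22 active-phase rates (normally above the weak-phase
#'   ones; scenario transforms may push them below, which is allowed).
#' @param windows list of `c(start, end)` active windows (days), non-overlapping.
#' @return a `policing_schedule` carrying phase metadata understood by the
#'   scenario transforms ([scale_active_phase()], [add_active_phase()]).
#' @export
policing_two_phase <- function(eps11, eps21, eps12, eps22,
                               windows = list(c(20, 21))) {
  if (!is.list(windows)) windows <- list(windows)
  starts <- vapply(windows, `[`, numeric(1), 1L)
  ends <- vapply(windows, `[`, numeric(1), 2L)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (any(ends <= starts)) stop("active windows must have end > start")
  if (length(starts) > 1 && any(starts[-1] < ends[-length(ends)]))
    stop("active windows must not overlap")
  breaks <- as.numeric(rbind(starts, ends))
  nint <- length(breaks) + 1
  e1 <- rep(eps11, nint); e2 <- rep(eps21, nint)
  active_idx <- seq(2, nint - 1, by = 2)
  e1[active_idx] <- eps12; e2[active_idx] <- eps22
  sched <- policing_schedule(breaks, e1, e2)
  sched$phases <- list(weak = c(eps1 = eps11, eps2 = eps21),
                       strong = c(eps1 = eps12, eps2 = eps22),
                       windows = Map(c, starts, ends))
  sched
}

#' Evaluate the policing schedule at a time point
#'
#' @param t time in days (vectorised), `t >= 0`.
#' @param sched a [policing_schedule()].
#' @return a matrix with columns `eps1`, `eps2`, one row per time; beyond the
#'   last breakpoint the final pair extends by constant extrapolation.
#' @export
policing_at <- function(t, sched) {
  stopifnot(inherits(sched, "policing_schedule"))
  if (any(t < 0)) stop("t must be >= 0")
  idx <- findInterval(t, sched$breaks, left.open = FALSE) + 1L
  cbind(eps1 = sched$eps1[idx], eps2 = sched$eps2[idx])
}

#' @export
print.policing_schedule <- function(x, ...) {
  k <- length(x$breaks)
  cat("Piecewise-constant policing schedule:", k + 1, "interval(s)\n")
  starts <- c(0, x$breaks)
  ends <- c(x$breaks, Inf)
  for (i in seq_len(k + 1))
    cat(sprintf("  [%g, %g): eps1 = %g, eps2 = %g\n",
                starts[i], ends[i], x$eps1[i], x$eps2[i]))
  invisible(x)
}

#' Model parameters for the protest compartment model
#'
#' The dynamics move people between five groups: susceptible (S), novice
#' protesters (I), experienced protesters (C), retired (R) and detained (D).
#' Recruitment S -> I follows mass action through contacts with both protester
#' groups; novices mature (I -> C) or withdraw (I -> R) at constant per-capita
#' rates, while the withdrawal of experienced protesters decreases with total
#' crowd size N = I + C (collective effects, see [withdrawal_rate()]).
#' Detention rates are time-dependent and live in the `policing` schedule.
#'
#' @param beta1 transmission rate via novice contacts (per person per day).
#' @param beta2 transmission rate via experienced contacts (per person per day).
#' @param gamma retired -> susceptible return rate (per day).
#' @param chi novice -> experienced maturation rate (per day).
#' @param delta1 novice withdrawal rate; also the upper (small-crowd) limit of
#'   the collective withdrawal law (per day).
#' @param delta2 lower (large-crowd) asymptote of the withdrawal law (per day);
#'   `delta1 - delta2` quantifies the strength of collective effects.
#' @param c0 half-saturation crowd size of the withdrawal law (persons).
#' @param n Hill exponent of the withdrawal law (dimensionless).
#' @param eps3 detainee release rate D -> R (per day).
#' @param policing a [policing_schedule()] holding the detention rates
#'   `eps1(t)` (novices) and `eps2(t)` (experienced).
#' @return an object of class `protest_params`.
#' @export
protest_params <- function(beta1, beta2, gamma, chi, delta1, delta2,
                           c0, n, eps3, policing = policing_schedule()) {
  p <- list(beta1 = beta1, beta2 = beta2, gamma = gamma, chi = chi,
            delta1 = delta1, delta2 = delta2, c0 = c0, n = n, eps3 = eps3,
            policing = policing)
  validate_params(p)
  structure(p, class = "protest_params")
}

validate_params <- function(p) {
  v <- unlist(p[PAR_NAMES])
  if (any(!is.finite(v))) stop("all parameters must be finite")
  if (any(v < 0)) stop("all parameters must be non-negative")
  if (p$delta1 < p$delta2)
    stop("delta1 must be >= delta2 (withdrawal decreases with crowd size)")
  if (p$c0 <= 0 || p$n <= 0) stop("c0 and n must be positive")
  if (!inherits(p$policing, "policing_schedule"))
    stop("policing must be a policing_schedule")
  invisible(p)
}

#' @export
print.protest_params <- function(x, ...) {
  cat("Protest model parameters:\n")
  v <- unlist(x[PAR_NAMES])
  cat(paste0("  ", format(names(v), width = 7), " = ",
             signif(v, 6), collapse = "\n"), "\n")
  print(x$policing)
  invisible(x)
}

#' Collective withdrawal rate of experienced protesters
#'
#' Hill-type decreasing function of total protester number `N = I + C`:
#' `omega(N) = delta2 + (delta1 - delta2) * c0^n / (N^n + c0^n)`.
#' At `N = 0` it equals `delta1`, at `N = c0` the midpoint
#' `(delta1 + delta2) / 2`, and it tends to `delta2` for large crowds, so a
#' large movement retains its experienced core.
#'
#' @param N total number of protesters (persons), vectorised, `N >= 0`.
#' @param p a [protest_params()] object.
#' @return withdrawal rate(s) per day, in `[delta2, delta1]`.
#' @export
withdrawal_rate <- function(N, p) {
  stopifnot(inherits(p, "protest_params"))
  if (any(!is.finite(N)) || any(N < 0)) stop("N must be finite and >= 0")
  c0n <- p$c0^p$n
  p$delta2 + (p$delta1 - p$delta2) * c0n / (N^p$n + c0n)
}

#' Initial state for a protest run
#'
#' Splits a closed adult population into compartments at t = 0: `I0` novice
#' protesters, optionally `C0_init` experienced ones, everyone else
#' susceptible; retired, detained and the cumulative-arrest counter start at
#' zero.
#'
#' @param p_total total (adult) population, persons.
#' @param i0 initial novice protesters.
#' @param c0_init initial experienced protesters (default 0).
#' @return named numeric state vector `(S, I, C, R, D, A)`.
#' @export
initial_state <- function(p_total, i0, c0_init = 0) {
  if (i0 < 0 || c0_init < 0 || p_total < 0)
    stop("population counts must be non-negative")
  if (i0 + c0_init > p_total)
    stop("initial protesters exceed total population")
  c(S = p_total - i0 - c0_init, I = i0, C = c0_init, R = 0, D = 0, A = 0)
}

#' Time derivative of the model state
#'
#' Right-hand side of the compartment system, exposed mainly for testing and
#' didactic use; simulation goes through the compiled integrator in
#' [simulate_protests()]. The sum of the five population derivatives is zero
#' identically (the system is closed); the auxiliary `A` accumulates the
#' detention flux `eps1(t) I + eps2(t) C`.
#'
#' @param t time in days.
#' @param state named state vector `(S, I, C, R, D, A)`, non-negative.
#' @param p a [protest_params()] object.
#' @return named vector of derivatives.
#' @export
protest_rhs <- function(t, state, p) {
  stopifnot(inherits(p, "protest_params"))
  if (any(!is.finite(state))) stop("state must be finite")
  if (any(state[c("S", "I", "C", "R", "D")] < 0))
    stop("compartment sizes must be non-negative")
  eps <- policing_at(t, p$policing)
  e1 <- unname(eps[1, "eps1"])
  e2 <- unname(eps[1, "eps2"])
  S <- state[["S"]]; I <- state[["I"]]; C <- state[["C"]]
  R <- state[["R"]]; D <- state[["D"]]
  w <- withdrawal_rate(I + C, p)
  recruit <- p$beta1 * S * I + p$beta2 * S * C
  detained <- e1 * I + e2 * C
  c(S = -recruit + p$gamma * R,
    I = recruit - (p$chi + p$delta1 + e1) * I,
    C = p$chi * I - (w + e2) * C,
    R = p$delta1 * I + w * C - p$gamma * R + p$eps3 * D,
    D = detained - p$eps3 * D,
    A = detained)
}

# get/set parameters by name, including the schedule entries of a two-phase
# schedule (eps11, eps12, eps21, eps22); "eps1"/"eps2" alias the weak-phase
# values, matching the nine-parameter vector of the sensitivity analysis.
param_value <- function(p, name) {
  if (name %in% PAR_NAMES) return(p[[name]])
  ph <- p$policing$phases
  if (is.null(ph))
    stop("parameter '", name, "' requires a two-phase policing schedule")
  switch(name,
         eps1 = , eps11 = ph$weak[["eps1"]],
         eps2 = , eps21 = ph$weak[["eps2"]],
         eps12 = ph$strong[["eps1"]],
         eps22 = ph$strong[["eps2"]],
         stop("unknown parameter '", name, "'"))
}

param_set <- function(p, name, value) {
  if (name %in% PAR_NAMES) {
    p[[name]] <- value
    return(do.call(protest_params, p[c(PAR_NAMES, "policing")]))
  }
  ph <- p$policing$phases
  if (is.null(ph))
    stop("parameter '", name, "' requires a two-phase policing schedule")
  w1 <- ph$weak[["eps1"]]; w2 <- ph$weak[["eps2"]]
  s1 <- ph$strong[["eps1"]]; s2 <- ph$strong[["eps2"]]
  switch(name,
         eps1 = , eps11 = w1 <- value,
         eps2 = , eps21 = w2 <- value,
         eps12 = s1 <- value,
         eps22 = s2 <- value,
         stop("unknown parameter '", name, "'"))
  p$policing <- policing_two_phase(w1, w2, s1, s2, windows = ph$windows)
  do.call(protest_params, p[c(PAR_NAMES, "policing")])
}

param_values <- function(p, names) {
  vapply(names, param_value, numeric(1), p = p)
}

param_update <- function(p, values) {
  for (nm in names(values)) p <- param_set(p, nm, values[[nm]])
  p
}

#' Write / read model parameters as a JSON config
#'
#' Flat keys `beta1 ... eps3` plus the schedule as a list of
#' `{start, eps1, eps2}` intervals; two-phase metadata survives the round
#' trip.
#'
#' @param p a [protest_params()] object.
#' @param path file path.
#' @return `read_params()` returns a `protest_params`; `write_params()` its
#'   input, invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "protest_params"))
  sched <- p$policing
  cfg <- c(p[PAR_NAMES],
           list(schedule = data.frame(start = c(0, sched$breaks),
                                      eps1 = sched$eps1,
                                      eps2 = sched$eps2)))
  if (!is.null(sched$phases))
    cfg$two_phase <- list(weak = as.list(sched$phases$weak),
                          strong = as.list(sched$phases$strong),
                          windows = sched$phases$windows)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(p)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$two_phase)) {
    tp <- cfg$two_phase
    wins <- tp$windows
    if (is.matrix(wins)) wins <- lapply(seq_len(nrow(wins)), function(i) wins[i, ])
    sched <- policing_two_phase(tp$weak$eps1, tp$weak$eps2,
                                tp$strong$eps1, tp$strong$eps2,
                                windows = wins)
  } else {
    s <- cfg$schedule
    sched <- policing_schedule(s$start[-1], s$eps1, s$eps2)
  }
  protest_params(cfg$beta1, cfg$beta2, cfg$gamma, cfg$chi, cfg$delta1,
                 cfg$delta2, cfg$c0, cfg$n, cfg$eps3, policing = sched)
}
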