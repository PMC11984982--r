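#' Simulate the protest model
#'
#' Integrates the six-dimensional augmented system (five compartments plus the
#' cumulative-arrest integral) with an adaptive Dormand-Prince 5(4) scheme.
#' The integrator stops exactly at every policing-schedule breakpoint, so the
#' piecewise-constant detention rates are honoured without smearing, and at
#' every requested output time, so no interpolation is involved.
#'
#' @param p a [protest_params()] object.
#' @param init initial state from [initial_state()].
#' @param t_end integration horizon in days, `> 0`.
#' @param output_times times (days) at which the state is reported; default a
#'   daily grid `0:t_end`. Must lie within `[0, t_end]`.
#' @param rtol,atol relative / absolute solver tolerances. The defaults
#'   (1e-8, 1e-4 persons) suit populations of order 1e7 changing on a scale of
#'   days.
#' @return a `protest_trajectory`: list with `times`, a states matrix with
#'   columns `S, I, C, R, D, A` (clipped to zero where solver round-off dips
#'   marginally negative), and `meta` (parameters and solver settings).
#' @export
simulate_protests <- function(p, init, t_end,
                              output_times = NULL,
                              rtol = 1e-8, atol = 1e-4) {
  stopifnot(inherits(p, "protest_params"))
  if (t_end <= 0) stop("t_end must be positive")
  if (is.null(output_times)) output_times <- seq(0, t_end)
  output_times <- sort(unique(as.numeric(output_times)))
  if (any(output_times < 0) || any(output_times > t_end + 1e-9))
    stop("output_times must lie in [0, t_end]")
  if (length(init) != 6) stop("init must have 6 components (S,I,C,R,D,A)")

  sched <- p$policing
  raw <- integrate_protest_cpp(unlist(p[PAR_NAMES]), sched$breaks,
                               sched$eps1, sched$eps2, as.numeric(init),
                               output_times, t_end, rtol, atol)
  states <- raw[, -1, drop = FALSE]
  colnames(states) <- c("S", "I", "C", "R", "D", "A")

  p0 <- sum(init[1:5])
  slack <- 1e-6 * p0
  if (any(states < -slack))
    warning("trajectory has negative compartments beyond solver slack")
  states[states < 0] <- 0

  structure(list(times = raw[, 1], states = states,
                 meta = list(params = p, init = init, t_end = t_end,
                             rtol = rtol, atol = atol, p_total = p0)),
            class = "protest_trajectory")
}

#' @export
print.protest_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Protest trajectory: %d time points on [%g, %g] days\n",
              n, x$times[1], x$times[n]))
  pa <- x$states[, "I"] + x$states[, "C"]
  cat(sprintf("  participants: start %.0f, peak %.0f (day %g), end %.0f\n",
              pa[1], max(pa), x$times[which.max(pa)], pa[n]))
  cat(sprintf("  cumulative arrests at end: %.0f\n", x$states[n, "A"]))
  invisible(x)
}

#' @export
as.data.frame.protest_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states,
             participants = x$states[, "I"] + x$states[, "C"])
}

traj_interp <- function(traj, column, times) {
  span <- range(traj$times)
  if (any(times < span[1] - 1e-9) || any(times > span[2] + 1e-9))
    stop("requested time outside trajectory span [",
         span[1], ", ", span[2], "]")
  approx(traj$times, traj$states[, column], xout = times, rule = 2)$y
}

#' Number of street protesters over time
#'
#' The observable used throughout the analysis: `I(t) + C(t)`, the sum of
#' novice and experienced protesters. Values at times between stored grid
#' points are linearly interpolated.
#'
#' @param traj a trajectory from [simulate_protests()].
#' @param times days at which to report; default the stored grid.
#' @return numeric vector of participant counts.
#' @export
participants <- function(traj, times = traj$times) {
  stopifnot(inherits(traj, "protest_trajectory"))
  traj_interp(traj, "I", times) + traj_interp(traj, "C", times)
}

#' Arrests accumulated over a time window
#'
#' `A(b) - A(a)` where `A` integrates the detention flux
#' `eps1(t) I + eps2(t) C`; this is what arrest records report. A record
#' phrased as "on day d" corresponds to the window `[d - 1, d]`.
#'
#' @param traj a trajectory from [simulate_protests()].
#' @param a,b window endpoints in days, `0 <= a <= b <=` span.
#' @return arrests in the window (persons).
#' @export
arrests_in_window <- function(traj, a, b) {
  stopifnot(inherits(traj, "protest_trajectory"))
  if (a > b) stop("window must have a <= b")
  traj_interp(traj, "A", b) - traj_interp(traj, "A", a)
}

#' Duration of the protest wave
#'
#' The smallest stored time T after which the participant count `I + C` stays
#' below `threshold` for every stored time `>= T`. Returns 0 when the
#' trajectory is below the threshold from the start and the span when it
#' never stays below (protests continue through the horizon). Read on the
#' stored output grid: observations are daily/weekly, so sub-day precision
#' would be spurious.
#'
#' @param traj a trajectory from [simulate_protests()].
#' @param threshold positive participant count defining "termination"
#'   (default 1000 persons).
#' @return duration in days.
#' @export
protest_duration <- function(traj, threshold = 1000) {
  stopifnot(inherits(traj, "protest_trajectory"))
  if (threshold <= 0) stop("threshold must be positive")
  pa <- traj$states[, "I"] + traj$states[, "C"]
  above <- which(pa >= threshold)
  if (!length(above)) return(0)
  j <- max(above)
  if (j == length(pa)) return(traj$times[length(pa)])
  traj$times[j + 1]
}

#' Export a trajectory as CSV
#'
#' Columns `time, S, I, C, R, D, A, participants`.
#'
#' @param traj a trajectory from [simulate_protests()].
#' @param path output file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(format(as.data.frame(traj), digits = 15, trim = TRUE,
                   scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(traj)
}
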