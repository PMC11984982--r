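# Counterfactual policing experiments: each transform returns a new
# parameter object; simulate and summarize to compare against the reference.

#' Remove policing entirely
#'
#' Replaces the schedule with all-zero detention rates (the "what if the
#' police had not intervened" counterfactual). Idempotent.
#'
#' @param p a [protest_params()] object.
#' @return a [protest_params()] with zero detention rates everywhere.
#' @export
no_policing <- function(p) {
  stopifnot(inherits(p, "protest_params"))
  p$policing <- policing_schedule()
  validate_params(p)
  p
}

#' Scale the active-phase detention rates
#'
#' Raises (or lowers) the active-window rates by `delta` percent:
#' `eps12 -> (1 + delta/100) eps12`, `eps22 -> (1 + delta/100) eps22`,
#' weak-phase values untouched. With `novice_only = TRUE` only the novice
#' rate `eps12` is scaled (experienced protesters assumed harder to catch).
#'
#' @param p a [protest_params()] whose schedule carries two-phase metadata
#'   (see [policing_two_phase()]).
#' @param delta percentage change, `>= -100`.
#' @param novice_only scale only the novice active rate.
#' @return a [protest_params()] with the rescaled schedule.
#' @export
scale_active_phase <- function(p, delta, novice_only = FALSE) {
  stopifnot(inherits(p, "protest_params"))
  if (delta < -100) stop("delta below -100% would give a negative rate")
  ph <- p$policing$phases
  if (is.null(ph))
    stop("scale_active_phase needs a two-phase schedule (policing_two_phase)")
  f <- 1 + delta / 100
  s1 <- ph$strong[["eps1"]] * f
  s2 <- if (novice_only) ph$strong[["eps2"]] else ph$strong[["eps2"]] * f
  p$policing <- policing_two_phase(ph$weak[["eps1"]], ph$weak[["eps2"]],
                                   s1, s2, windows = ph$windows)
  validate_params(p)
  p
}

#' Add an extra one-day active phase
#'
#' Inserts an additional active window `[day, day + 1)` with the existing
#' strong pair `(eps12, eps22)` — the "second crackdown" experiment.
#'
#' @param p a [protest_params()] with a two-phase schedule.
#' @param day start of the new window (days); must not overlap an existing
#'   active window.
#' @return a [protest_params()] with the extended schedule.
#' @export
add_active_phase <- function(p, day) {
  stopifnot(inherits(p, "protest_params"))
  ph <- p$policing$phases
  if (is.null(ph))
    stop("add_active_phase needs a two-phase schedule (policing_two_phase)")
  for (w in ph$windows)
    if (day < w[2] && day + 1 > w[1])
      stop("new active window [", day, ", ", day + 1,
           ") overlaps existing window [", w[1], ", ", w[2], ")")
  p$policing <- policing_two_phase(ph$weak[["eps1"]], ph$weak[["eps2"]],
                                   ph$strong[["eps1"]], ph$strong[["eps2"]],
                                   windows = c(ph$windows, list(c(day, day + 1))))
  validate_params(p)
  p
}

#' Sustained increase of policing from a given day
#'
#' Multiplies whatever detention rates the schedule holds at `t >= from_day`
#' by `1 + delta/100`; the schedule before `from_day` is unchanged. Unlike a
#' short active phase this models a lasting shift to a harsher policing mode.
#' The two-phase metadata is dropped (the result is a general schedule).
#'
#' @param p a [protest_params()] object.
#' @param delta percentage increase, `>= -100`.
#' @param from_day day from which the increase applies.
#' @return a [protest_params()] with the modified schedule.
#' @export
sustained_increase <- function(p, delta, from_day) {
  stopifnot(inherits(p, "protest_params"))
  if (delta < -100) stop("delta below -100% would give a negative rate")
  f <- 1 + delta / 100
  s <- p$policing
  breaks <- s$breaks
  e1 <- s$eps1; e2 <- s$eps2
  if (!(from_day %in% c(0, breaks))) {
    # split the interval containing from_day
    i <- findInterval(from_day, breaks) + 1L
    breaks <- sort(c(breaks, from_day))
    e1 <- append(e1, e1[i], after = i)
    e2 <- append(e2, e2[i], after = i)
  }
  starts <- c(0, breaks)
  late <- starts >= from_day
  e1[late] <- e1[late] * f
  e2[late] <- e2[late] * f
  p$policing <- policing_schedule(breaks, e1, e2)
  validate_params(p)
  p
}

#' Summary statistics of a simulated protest wave
#'
#' @param traj a trajectory from [simulate_protests()].
#' @param threshold termination threshold for [protest_duration()] (persons).
#' @return an object of class `scenario_summary` with `peak` (persons),
#'   `peak_day`, `duration` (days), `person_days` (trapezoidal integral of
#'   `I + C`) and `total_arrests` (final value of the arrest integral).
#' @export
summarize_trajectory <- function(traj, threshold = 1000) {
  stopifnot(inherits(traj, "protest_trajectory"))
  pa <- traj$states[, "I"] + traj$states[, "C"]
  tt <- traj$times
  k <- which.max(pa)
  person_days <- sum(diff(tt) * (pa[-1] + pa[-length(pa)]) / 2)
  structure(list(peak = pa[k], peak_day = tt[k],
                 duration = protest_duration(traj, threshold),
                 person_days = person_days,
                 total_arrests = traj$states[nrow(traj$states), "A"]),
            class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf(paste0("Scenario summary: peak %.0f protesters on day %g, ",
                     "duration %g days,\n  %.4g person-days, ",
                     "%.0f total arrests\n"),
              x$peak, x$peak_day, x$duration, x$person_days,
              x$total_arrests))
  invisible(x)
}

#' @export
as.data.frame.scenario_summary <- function(x, ...) {
  data.frame(peak = x$peak, peak_day = x$peak_day, duration = x$duration,
             person_days = x$person_days, total_arrests = x$total_arrests)
}
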