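#' Observation set: participant counts plus heterogeneous arrest records
#'
#' Real arrest data come in mixed dialects: cumulative counts over an
#' interval of days ("8700 arrested between days 1-126") and single-day
#' counts ("1500 on day 21"). Both are kept as records against the model's
#' cumulative-arrest integral; a single-day record at day `d` maps to the
#' window `[d - 1, d]`.
#'
#' @param participant_obs data frame with columns `day`, `count` (at least one
#'   row).
#' @param arrest_obs optional data frame with columns `kind`
#'   (`"interval_cumulative"` or `"single_day"`), `start`, `end`, `count`;
#'   single-day records use `start == end == d`.
#' @return an object of class `observation_set`.
#' @export
observation_set <- function(participant_obs, arrest_obs = NULL) {
  participant_obs <- as.data.frame(participant_obs)
  if (!all(c("day", "count") %in% names(participant_obs)))
    stop("participant_obs needs columns 'day' and 'count'")
  if (nrow(participant_obs) < 1)
    stop("need at least one participant observation")
  if (any(participant_obs$day < 0) || any(participant_obs$count < 0))
    stop("participant days and counts must be non-negative")
  if (is.null(arrest_obs)) {
    arrest_obs <- data.frame(kind = character(0), start = numeric(0),
                             end = numeric(0), count = numeric(0))
  } else {
    arrest_obs <- as.data.frame(arrest_obs)
    if (!all(c("kind", "start", "end", "count") %in% names(arrest_obs)))
      stop("arrest_obs needs columns 'kind', 'start', 'end', 'count'")
    if (!all(arrest_obs$kind %in% c("interval_cumulative", "single_day")))
      stop("arrest record kind must be 'interval_cumulative' or 'single_day'")
    if (any(arrest_obs$start < 0) || any(arrest_obs$end < arrest_obs$start))
      stop("arrest windows must be well-ordered and non-negative")
    if (any(arrest_obs$count < 0)) stop("arrest counts must be non-negative")
    sd <- arrest_obs$kind == "single_day"
    if (any(arrest_obs$end[sd] != arrest_obs$start[sd]))
      stop("single_day records must have start == end")
  }
  structure(list(participant_obs = participant_obs, arrest_obs = arrest_obs),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("Observation set: %d participant counts (days %g..%g), %d arrest record(s)\n",
              nrow(x$participant_obs), min(x$participant_obs$day),
              max(x$participant_obs$day), nrow(x$arrest_obs)))
  invisible(x)
}

#' Restrict observations to a training window
#'
#' Keeps participant observations with `day <= t_max` and arrest records fully
#' contained in `[0, t_max]` — the "training set" used to probe the model's
#' predictive power beyond the fitted window.
#'
#' @param obs an [observation_set()].
#' @param t_max last day retained.
#' @return an [observation_set()].
#' @export
truncate_observations <- function(obs, t_max) {
  stopifnot(inherits(obs, "observation_set"))
  observation_set(obs$participant_obs[obs$participant_obs$day <= t_max, ],
                  obs$arrest_obs[obs$arrest_obs$end <= t_max, ])
}

# horizon needed to evaluate every record of an observation set
obs_horizon <- function(obs) {
  max(obs$participant_obs$day, obs$arrest_obs$end, 1)
}

# simulate once on a grid fine enough for all records of obs
obs_simulate <- function(p, init, obs, rtol = 1e-8, atol = 1e-4) {
  t_end <- obs_horizon(obs)
  sd <- obs$arrest_obs$kind == "single_day"
  times <- sort(unique(c(0, obs$participant_obs$day,
                         obs$arrest_obs$start, obs$arrest_obs$end,
                         pmax(obs$arrest_obs$start[sd] - 1, 0), t_end)))
  simulate_protests(p, init, t_end, output_times = times,
                    rtol = rtol, atol = atol)
}

#' Model predictions aligned to an observation set
#'
#' Participant records predict `I + C` at the observation day; interval
#' cumulative arrest records predict `A(b) - A(a)`; single-day records at day
#' `d` predict `A(d) - A(d - 1)`.
#'
#' @param p a [protest_params()] object.
#' @param init initial state.
#' @param obs an [observation_set()].
#' @param rtol,atol solver tolerances passed to [simulate_protests()].
#' @return list with numeric vectors `participants` and `arrests`, aligned
#'   row-by-row with the observation tables.
#' @export
predict_observables <- function(p, init, obs, rtol = 1e-8, atol = 1e-4) {
  stopifnot(inherits(obs, "observation_set"))
  traj <- obs_simulate(p, init, obs, rtol, atol)
  arr <- obs$arrest_obs
  a <- ifelse(arr$kind == "single_day", pmax(arr$start - 1, 0), arr$start)
  arrests <- if (nrow(arr)) {
    vapply(seq_len(nrow(arr)),
           function(i) arrests_in_window(traj, a[i], arr$end[i]), numeric(1))
  } else numeric(0)
  list(participants = participants(traj, obs$participant_obs$day),
       arrests = arrests)
}

#' Relative least-squares misfit
#'
#' Weighted sum of squared relative residuals,
#' `w_part * sum(((pred - obs) / max(obs, 1))^2)` over participant records
#' plus the analogous arrest term. Relative residuals are used because counts
#' span 1e3-1e5: absolute squares would let the first weeks dominate
#' completely. The denominator floor of 1 person guards against zero counts.
#' A solver failure inside the prediction yields a large penalty value (with a
#' warning) instead of an error, which keeps derivative-free optimizers alive.
#'
#' @param p a [protest_params()] object.
#' @param init initial state.
#' @param obs an [observation_set()].
#' @param weights length-2 non-negative vector `(participants, arrests)`, not
#'   both zero.
#' @param rtol,atol solver tolerances.
#' @return non-negative scalar; zero iff every prediction matches its record.
#' @export
misfit <- function(p, init, obs, weights = c(1, 1),
                   rtol = 1e-8, atol = 1e-4) {
  if (length(weights) != 2 || any(weights < 0) || sum(weights) == 0)
    stop("weights must be two non-negative numbers, not both zero")
  pred <- tryCatch(predict_observables(p, init, obs, rtol, atol),
                   error = function(e) {
                     warning("solver failure in misfit: ",
                             conditionMessage(e))
                     NULL
                   })
  if (is.null(pred)) return(1e12)
  rp <- (pred$participants - obs$participant_obs$count) /
    pmax(obs$participant_obs$count, 1)
  ra <- if (nrow(obs$arrest_obs)) {
    (pred$arrests - obs$arrest_obs$count) / pmax(obs$arrest_obs$count, 1)
  } else numeric(0)
  weights[1] * sum(rp^2) + weights[2] * sum(ra^2)
}

#' Configuration of an inverse-problem fit
#'
#' @param params full [protest_params()] template; fixed parameters keep these
#'   values, free parameters are initialised at and bounded around them (the
#'   template is the user's rough prior guess and is always used as the first
#'   local-search start).
#' @param free names of the parameters to estimate. The default is the
#'   identifiable structural core of the model (the package's own orthogonal
#'   ranking puts the weak-phase detention rates `eps1`, `eps2` five to seven
#'   orders of magnitude below the leading parameters, and `gamma`, `eps3` do
#'   not measurably affect the participant observable); any of
#'   `eps1`/`eps11`, `eps2`/`eps21`, `eps12`, `eps22`, `gamma`, `eps3` may be
#'   added to the mask.
#' @param lower,upper optional named bounds; by default a factor
#'   `bounds_factor` box around the template values.
#' @param bounds_factor multiplicative half-width of the default box.
#' @param weights misfit weights `(participants, arrests)`.
#' @param n_starts population size of the global (differential-evolution)
#'   search stage; its initial population is a seeded Latin hypercube over
#'   the bounds box. Set alongside `global_rounds = 0` to skip the global
#'   stage entirely.
#' @param seed integer seed; the fit is deterministic given observations,
#'   config and seed.
#' @param maxit generations per differential-evolution round.
#' @param global_rounds maximum number of global-search rounds run when the
#'   local polish of the template does not already reach `ftol` (0 = local
#'   search only).
#' @param cascade_cycles maximum Levenberg-Marquardt / Nelder-Mead
#'   alternation cycles per polish.
#' @param ftol objective value regarded as a converged (essentially exact)
#'   fit; noise-free recovery reaches it, noisy fits stop on stagnation
#'   instead.
#' @param polish logical; run the local cascade at all (disable only for
#'   debugging the global stage).
#' @param rtol,atol solver tolerances used inside the objective. Tighter than
#'   the simulation defaults because the late, small participant counts
#'   otherwise inherit solver noise of the order of the population times
#'   `rtol`, which poisons finite-difference steps.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(params,
                       free = c("beta1", "beta2", "chi", "n", "c0",
                                "delta1", "delta2"),
                       lower = NULL, upper = NULL, bounds_factor = 10,
                       weights = c(1, 1), n_starts = 40, seed = 1,
                       maxit = 400, global_rounds = 3, cascade_cycles = 15,
                       ftol = 5e-7, polish = TRUE,
                       rtol = 1e-10, atol = 1e-6) {
  stopifnot(inherits(params, "protest_params"))
  centre <- param_values(params, free)
  lo <- centre / bounds_factor
  hi <- centre * bounds_factor
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  floor_ <- pmax(hi, 1e-300) * 1e-8
  lo <- pmax(lo, floor_)  # log-scale parameterisation needs positive bounds
  if (any(hi < lo)) stop("upper bounds must be >= lower bounds")
  bad <- centre < lo | centre > hi
  if (any(bad))
    stop("template value outside bounds for: ",
         paste(free[bad], collapse = ", "))
  structure(list(params = params, free = free, lower = lo, upper = hi,
                 weights = weights, n_starts = n_starts, seed = seed,
                 maxit = maxit, global_rounds = global_rounds,
                 cascade_cycles = cascade_cycles, ftol = ftol,
                 polish = polish, rtol = rtol, atol = atol),
            class = "fit_config")
}

# run expr with a private RNG stream, restoring the global one afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Latin hypercube on (0,1)^d: one point per row
latin_hypercube <- function(n, d) {
  u <- matrix(runif(n * d), n, d)
  for (j in seq_len(d)) u[, j] <- (sample.int(n) - u[, j]) / n
  u
}

#' Fit the protest model to observations
#'
#' Bounded minimisation of [misfit()] over the free parameters on a log
#' scale, which keeps everything positive and equalises steps across
#' parameters spanning orders of magnitude. The landscape of the relative
#' least-squares objective is extremely anisotropic for this model (the
#' identifiable directions are orders of magnitude stiffer than the rest, and
#' trajectories near the collapse phase respond violently to small parameter
#' changes), so the fit is organised as:
#'
#' 1. a local "cascade" from the template parameters — alternating damped
#'    Gauss-Newton (Levenberg-Marquardt on the residual vector, with
#'    central-difference Jacobians, step clamping and box projection) with
#'    Nelder-Mead sweeps, which follows the curved, ill-conditioned valley
#'    where either method alone stagnates; and
#' 2. if the cascade does not reach `ftol`, up to `global_rounds` rounds of a
#'    seeded differential-evolution search (population `n_starts`,
#'    initialised by Latin hypercube over the bounds box) on a log-scale
#'    shape-matching surrogate (level plus week-to-week slope of the
#'    participant series), whose best members are polished by the same
#'    cascade.
#'
#' Deterministic given `(obs, init, cfg)` including the seed stored in `cfg`.
#'
#' @param obs an [observation_set()].
#' @param init initial state.
#' @param cfg a [fit_config()].
#' @return an object of class `fit_result`: `q_hat` (full
#'   [protest_params()]), `par` (named free-parameter estimates), `objective`,
#'   `start_objectives` (objective after each polish), `converged` (reached
#'   `ftol` or stagnated at a local optimum), `n_evaluations`.
#' @export
fit_protests <- function(obs, init, cfg) {
  stopifnot(inherits(obs, "observation_set"), inherits(cfg, "fit_config"))
  free <- cfg$free
  d <- length(free)

  if (d == 0) {
    val <- misfit(cfg$params, init, obs, cfg$weights, cfg$rtol, cfg$atol)
    return(structure(list(q_hat = cfg$params, par = numeric(0),
                          objective = val, start_objectives = val,
                          converged = TRUE, n_evaluations = 1L),
                     class = "fit_result"))
  }

  zlo <- log(cfg$lower)
  zhi <- log(cfg$upper)
  sw <- sqrt(cfg$weights)
  obsvec <- c(obs$participant_obs$count, obs$arrest_obs$count)
  npart <- nrow(obs$participant_obs)
  wvec <- c(rep(sw[1], npart), rep(sw[2], length(obsvec) - npart))
  lobs <- log1p(obsvec)
  dlobs <- diff(lobs[seq_len(npart)])
  nev <- 0L

  predict_at <- function(z, rtol, atol) {
    nev <<- nev + 1L
    q <- exp(pmin(pmax(z, zlo), zhi))
    p <- tryCatch(param_update(cfg$params, setNames(as.list(q), free)),
                  error = function(e) NULL)
    if (is.null(p)) return(NULL)
    pr <- tryCatch(predict_observables(p, init, obs, rtol, atol),
                   error = function(e) NULL)
    if (is.null(pr)) return(NULL)
    c(pr$participants, pr$arrests)
  }
  # weighted relative residuals; sum of squares equals misfit() exactly
  resid_z <- function(z) {
    pv <- predict_at(z, cfg$rtol, cfg$atol)
    if (is.null(pv)) return(rep(1e3, length(obsvec)))
    wvec * (pv - obsvec) / pmax(obsvec, 1)
  }
  obj_z <- function(z) sum(resid_z(z)^2)
  # surrogate for the global stage: log-level plus week-to-week log-slope of
  # the participant series (cheap solver tolerances; shape beats level here)
  obj_surrogate <- function(z) {
    pv <- predict_at(z, 1e-8, 1e-4)
    if (is.null(pv)) return(1e6)
    lp <- log1p(pv)
    sum((lp - lobs)^2) +
      3 * sum((diff(lp[seq_len(npart)]) - dlobs)^2)
  }

  lm_step <- function(z, maxit = 60) {
    r <- resid_z(z)
    f <- sum(r^2)
    lam <- 1e-2
    for (it in seq_len(maxit)) {
      J <- matrix(0, length(r), d)
      for (j in seq_len(d)) {
        h <- 1e-5
        zp <- z; zp[j] <- z[j] + h
        zm <- z; zm[j] <- z[j] - h
        J[, j] <- (resid_z(zp) - resid_z(zm)) / (2 * h)
      }
      g <- crossprod(J, r)
      H <- crossprod(J)
      dH <- diag(H) + 0.01 * mean(diag(H)) + 1e-12
      ok <- FALSE
      for (tries in 1:40) {
        dz <- tryCatch(solve(H + lam * diag(dH, d), -g),
                       error = function(e) NULL)
        if (!is.null(dz)) {
          dz <- pmin(pmax(as.numeric(dz), -0.5), 0.5)
          zn <- pmin(pmax(z + dz, zlo), zhi)
          rn <- resid_z(zn)
          fn <- sum(rn^2)
          if (is.finite(fn) && fn < f) {
            z <- zn; r <- rn; f <- fn
            lam <- max(lam / 4, 1e-12)
            ok <- TRUE
            break
          }
        }
        lam <- lam * 7
        if (lam > 1e13) break
      }
      if (!ok || f < 1e-10) break
    }
    list(par = z, value = f)
  }

  cascade <- function(z0) {
    cur <- list(par = pmin(pmax(z0, zlo), zhi), value = obj_z(z0))
    stagnant <- 0L
    for (cycle in seq_len(cfg$cascade_cycles)) {
      prev <- cur$value
      cur <- lm_step(cur$par)
      nm <- optim(cur$par, obj_z, method = "Nelder-Mead",
                  control = list(maxit = 2500, reltol = 1e-14))
      if (nm$value < cur$value) cur <- nm
      if (cur$value < cfg$ftol) break
      stagnant <- if (prev - cur$value < 1e-2 * prev) stagnant + 1L else 0L
      if (stagnant >= 3L) break
    }
    cur
  }

  de_round <- function(np, gens, k = 2) {
    u <- latin_hypercube(np, d)
    pop <- t(zlo + t(u) * (zhi - zlo))
    pop[1, ] <- log(pmin(pmax(param_values(cfg$params, free),
                              cfg$lower), cfg$upper))  # template member
    fit <- apply(pop, 1, obj_surrogate)
    for (g in seq_len(gens)) {
      Fw <- runif(1, 0.5, 1.0)
      for (i in seq_len(np)) {
        idx <- sample(seq_len(np)[-i], 3)
        v <- pop[idx[1], ] + Fw * (pop[idx[2], ] - pop[idx[3], ])
        cross <- runif(d) < 0.9
        cross[sample.int(d, 1)] <- TRUE
        u1 <- pmin(pmax(ifelse(cross, v, pop[i, ]), zlo), zhi)
        fu <- obj_surrogate(u1)
        if (fu <= fit[i]) {
          pop[i, ] <- u1
          fit[i] <- fu
        }
      }
    }
    lapply(order(fit)[seq_len(k)],
           function(b) list(par = pop[b, ], value = fit[b]))
  }

  run <- function() {
    z_template <- log(pmin(pmax(param_values(cfg$params, free),
                                cfg$lower), cfg$upper))
    best <- if (cfg$polish) cascade(z_template) else
      list(par = z_template, value = obj_z(z_template))
    polish_obj <- best$value
    if (best$value >= cfg$ftol && cfg$global_rounds > 0) {
      for (round in seq_len(cfg$global_rounds)) {
        prev_best <- best$value
        cands <- de_round(cfg$n_starts, cfg$maxit)
        for (cand in cands) {
          cur <- if (cfg$polish) cascade(cand$par) else
            list(par = cand$par, value = obj_z(cand$par))
          polish_obj <- c(polish_obj, cur$value)
          if (cur$value < best$value) best <- cur
          if (best$value < cfg$ftol) break
        }
        if (best$value < cfg$ftol) break
        # stop early when a whole round brings <1% improvement (noisy data:
        # the objective floor is set by the noise, not by convergence)
        if (prev_best - best$value < 1e-2 * prev_best) break
      }
    }
    list(best = best, polish_obj = polish_obj)
  }

  out <- with_seed(cfg$seed, run())
  best <- out$best
  q <- exp(pmin(pmax(best$par, zlo), zhi))
  names(q) <- free
  structure(list(q_hat = param_update(cfg$params, setNames(as.list(q), free)),
                 par = q, objective = best$value,
                 start_objectives = out$polish_obj,
                 converged = best$value < cfg$ftol || cfg$polish,
                 n_evaluations = nev),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Protest model fit\n")
  cat(sprintf("  objective: %.6g  (%d evaluations, converged: %s)\n",
              x$objective, x$n_evaluations, x$converged))
  if (length(x$par)) {
    cat("  estimates:\n")
    cat(paste0("    ", format(names(x$par), width = 7), " = ",
               signif(x$par, 6), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Read / write observation CSV files
#'
#' `participants.csv` has header `day,participants`; `arrests.csv` has header
#' `kind,start,end,count` (single-day records use `start == end`).
#'
#' @param participants_path path to the participants CSV.
#' @param arrests_path optional path to the arrests CSV.
#' @return an [observation_set()].
#' @export
read_observations <- function(participants_path, arrests_path = NULL) {
  pp <- read.csv(participants_path)
  if (!all(c("day", "participants") %in% names(pp)))
    stop("participants file must have columns 'day' and 'participants'")
  arr <- NULL
  if (!is.null(arrests_path)) {
    arr <- read.csv(arrests_path)
    if (!all(c("kind", "start", "end", "count") %in% names(arr)))
      stop("arrests file must have columns 'kind', 'start', 'end', 'count'")
  }
  observation_set(data.frame(day = pp$day, count = pp$participants), arr)
}

#' @rdname read_observations
#' @param obs an [observation_set()] to write.
#' @export
write_observations <- function(obs, participants_path, arrests_path = NULL) {
  stopifnot(inherits(obs, "observation_set"))
  write.csv(data.frame(day = obs$participant_obs$day,
                       participants = obs$participant_obs$count),
            participants_path, row.names = FALSE, quote = FALSE)
  if (!is.null(arrests_path))
    write.csv(obs$arrest_obs, arrests_path, row.names = FALSE, quote = FALSE)
  invisible(obs)
}
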