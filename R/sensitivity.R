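#' Semi-relative sensitivity matrix
#'
#' Entries `s_ij = q_j * d f(t_i, q) / d q_j` for an observable `f` at
#' measurement times `t_i` — scaling by the parameter value makes columns
#' comparable across parameters of very different magnitudes. Derivatives are
#' central finite differences with relative step `rel_step` (absolute
#' fallback step when a parameter is exactly zero), each perturbation
#' re-integrating the system; the solver tolerances default tighter than for
#' plain simulation so that differencing noise stays well below the
#' truncation error of the stencil.
#'
#' @param p a [protest_params()] object (reference point).
#' @param init initial state.
#' @param times measurement days.
#' @param observable `"participants"` for `I + C`, or one of
#'   `"S", "I", "C", "R", "D"`.
#' @param free parameter names giving the columns; defaults to the
#'   nine-parameter vector (`eps1`, `eps2` are the weak-phase detention
#'   rates).
#' @param rel_step relative finite-difference step.
#' @param abs_step absolute step used when a parameter value is zero.
#' @param rtol,atol solver tolerances for the perturbed runs.
#' @return a numeric matrix of class `sensitivity_matrix` (rows = times,
#'   columns = parameters) with attributes `times`, `observable`.
#' @export
sensitivity_matrix <- function(p, init, times,
                               observable = "participants",
                               free = c("beta1", "beta2", "chi", "n", "c0",
                                        "delta1", "delta2", "eps1", "eps2"),
                               rel_step = 1e-5, abs_step = 1e-8,
                               rtol = 1e-10, atol = 1e-8) {
  stopifnot(inherits(p, "protest_params"))
  t_end <- max(times, 1)
  extract <- function(q) {
    traj <- simulate_protests(q, init, t_end, output_times = sort(unique(times)),
                              rtol = rtol, atol = atol)
    if (observable == "participants") participants(traj, times)
    else traj_interp(traj, observable, times)
  }
  S <- matrix(0, length(times), length(free),
              dimnames = list(NULL, free))
  for (j in seq_along(free)) {
    qj <- param_value(p, free[j])
    h <- if (qj == 0) {
      message("parameter ", free[j], " is zero: using absolute step")
      abs_step
    } else rel_step * abs(qj)
    fp <- extract(param_set(p, free[j], qj + h))
    fm <- extract(param_set(p, free[j], max(qj - h, 0)))
    hm <- qj - max(qj - h, 0)  # one-sided shrink if qj < h
    S[, j] <- qj * (fp - fm) / (h + hm)
  }
  structure(S, times = times, observable = observable,
            class = c("sensitivity_matrix", "matrix"))
}

#' Greedy orthogonal identifiability ranking
#'
#' Ranks parameters from most to least identifiable by the orthogonal method:
#' pick the sensitivity-matrix column with the largest sum of squares, then
#' repeatedly project the remaining (original) columns onto the orthogonal
#' complement of the span of the selected ones and pick the column with the
#' largest perpendicular norm. A perpendicular norm near zero flags a
#' parameter whose effect on the observable can be compensated by the
#' already-selected ones (practical non-identifiability). Ties are broken by
#' column order (first wins) for determinism.
#'
#' @param S a [sensitivity_matrix()] (or any numeric matrix with named
#'   columns).
#' @return an object of class `identifiability_ranking`: `order` (column
#'   names, most to least identifiable) and `perp_norms` (the Euclidean norm
#'   of the selected perpendicular at each iteration).
#' @export
orthogonal_rank <- function(S) {
  S <- unclass(as.matrix(S))
  if (is.null(colnames(S))) colnames(S) <- paste0("q", seq_len(ncol(S)))
  if (!all(is.finite(S))) stop("sensitivity matrix must be finite")
  if (all(S == 0)) stop("zero sensitivity matrix: nothing is identifiable")
  n <- nrow(S); J <- ncol(S)
  if (n < J)
    warning("fewer measurement times than parameters (", n, " < ", J,
            "): ranking may be degenerate")
  remaining <- seq_len(J)
  Q <- matrix(0, n, 0)
  ord <- integer(0)
  norms <- numeric(0)
  while (length(remaining)) {
    perp2 <- vapply(remaining, function(j) {
      v <- S[, j]
      if (ncol(Q)) v <- v - Q %*% crossprod(Q, v)
      sum(v^2)
    }, numeric(1))
    k <- remaining[which.max(perp2)]  # which.max takes the first maximum
    v <- S[, k]
    if (ncol(Q)) v <- v - Q %*% crossprod(Q, v)
    nv <- sqrt(sum(v^2))
    ord <- c(ord, k)
    norms <- c(norms, nv)
    if (nv > 1e-300) Q <- cbind(Q, v / nv)
    remaining <- setdiff(remaining, k)
  }
  structure(list(order = colnames(S)[ord], perp_norms = norms),
            class = "identifiability_ranking")
}

#' @export
print.identifiability_ranking <- function(x, ...) {
  cat("Identifiability ranking (most -> least identifiable):\n")
  for (i in seq_along(x$order))
    cat(sprintf("  %2d. %-7s  |perp| = %.6g\n", i, x$order[i],
                x$perp_norms[i]))
  invisible(x)
}

#' Export sensitivity results as CSV
#'
#' The sensitivity matrix is written as times x parameters; the ranking as
#' `iteration, parameter, log10_perp_norm` (log scale, as identifiability
#' plots are customarily drawn).
#'
#' @param S a [sensitivity_matrix()].
#' @param path output file path.
#' @export
write_sensitivity_csv <- function(S, path) {
  df <- data.frame(time = attr(S, "times"), unclass(S), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(S)
}

#' @rdname write_sensitivity_csv
#' @param ranking an [orthogonal_rank()] result.
#' @export
write_ranking_csv <- function(ranking, path) {
  df <- data.frame(iteration = seq_along(ranking$order),
                   parameter = ranking$order,
                   log10_perp_norm = log10(pmax(ranking$perp_norms,
                                                .Machine$double.xmin)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(ranking)
}
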