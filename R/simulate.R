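#' Solver settings
#'
#' The model is integrated with an adaptive explicit Runge-Kutta (2,3) pair
#' (Bogacki-Shampine, deSolve method `"ode23"`) at relative and absolute
#' error tolerances of 1e-8. Dense output is sampled every `output_dt` days;
#' the sampling grid is presentation only, the adaptive step controller is
#' driven purely by the tolerances.
#'
#' @param rtol Relative error tolerance (dimensionless).
#' @param atol Absolute error tolerance (mg L^-1).
#' @param method deSolve integrator name; any embedded explicit RK pair of
#'   order at least (2,3) is acceptable (e.g. `"ode45"` for cross-checks).
#' @param output_dt Output sampling interval (days).
#' @return Object of class `solver_settings`.
#' @export
solver_settings <- function(rtol = 1e-8, atol = 1e-8, method = "ode23",
                            output_dt = 0.1) {
  stopifnot(rtol > 0, atol > 0, output_dt > 0, is.character(method))
  structure(list(rtol = rtol, atol = atol, method = method,
                 output_dt = output_dt),
            class = "solver_settings")
}

output_times <- function(t_span, output_dt) {
  times <- seq(t_span[1], t_span[2], by = output_dt)
  if (times[length(times)] < t_span[2]) times <- c(times, t_span[2])
  times
}

new_trajectory <- function(out, params, settings, initial, t_span,
                           species = STATE_NAMES) {
  df <- as.data.frame(unclass(out))
  names(df) <- c("time", species)
  attr(df, "params") <- params
  attr(df, "settings") <- settings
  attr(df, "initial") <- initial
  attr(df, "t_span") <- t_span
  ist <- attr(out, "istate")
  if (!is.null(ist))
    attr(df, "solver_stats") <- c(steps = ist[2], rhs_evaluations = ist[3],
                                  error_test_failures = ist[13])
  class(df) <- c("dormprey_trajectory", "data.frame")
  df
}

check_trajectory_finite <- function(df, species) {
  m <- as.matrix(df[species])
  if (anyNA(m) || any(!is.finite(m))) {
    bad <- which(!stats::complete.cases(m) | rowSums(!is.finite(m)) > 0)[1]
    stop(sprintf("integration failed: non-finite state at t = %g",
                 df$time[bad]), call. = FALSE)
  }
  if (any(m < -1e-6))
    stop("integration failed: density undershoot beyond -1e-6 mg/L; ",
         "tighten tolerances", call. = FALSE)
  invisible(df)
}

#' Integrate the full four-compartment model
#'
#' Solves the model's rate equations from an initial state over a time span,
#' returning a dense, uniformly sampled trajectory. The integration is
#' deterministic: identical inputs give bit-identical trajectories.
#'
#' @param params A `dormprey_params` (see [dormprey_params()]).
#' @param initial Named initial state `(p, y1, y2, z)`; default
#'   [initial_state()] = (2, 2, 0, 1).
#' @param t_span Numeric `(start, end)` in days, `end > start >= 0`.
#' @param settings A [solver_settings()].
#' @param rhs `"compiled"` (default) evaluates the right-hand side in C;
#'   `"R"` uses [derivatives()]. Both encode the same equations; the
#'   compiled path exists because parameter sweeps run hundreds of
#'   integrations.
#' @return A `dormprey_trajectory`: a data frame with columns `time`, `p`,
#'   `y1`, `y2`, `z` and attributes `params`, `settings`, `initial`,
#'   `t_span`, `solver_stats`.
#' @examples
#' traj <- integrate_model(dormprey_params(), t_span = c(0, 100))
#' tail(traj)
#' @export
integrate_model <- function(params = dormprey_params(),
                            initial = initial_state(),
                            t_span = c(0, 3000),
                            settings = solver_settings(),
                            rhs = c("compiled", "R")) {
  params <- validate_params(params)
  initial <- validate_state(initial)
  rhs <- match.arg(rhs)
  stopifnot(length(t_span) == 2, t_span[2] > t_span[1], t_span[1] >= 0)
  times <- output_times(t_span, settings$output_dt)

  if (rhs == "compiled") {
    out <- deSolve::ode(y = unname(initial), times = times,
                        func = "dormprey_rhs", parms = unlist(params[PARAM_NAMES]),
                        dllname = "dormprey", initfunc = "dormprey_init",
                        method = settings$method,
                        rtol = settings$rtol, atol = settings$atol)
  } else {
    fn <- function(t, y, prm) {
      names(y) <- STATE_NAMES
      list(unname(derivatives(y, prm)))
    }
    out <- deSolve::ode(y = unname(initial), times = times, func = fn,
                        parms = params, method = settings$method,
                        rtol = settings$rtol, atol = settings$atol)
  }
  df <- new_trajectory(out, params, settings, initial, t_span)
  check_trajectory_finite(df, STATE_NAMES)
}

#' Integrate the two-species Rosenzweig-MacArthur reduction
#'
#' Integrates only the PA prey + predator subsystem (`y1 = y2 = 0`), with a
#' right-hand side coded independently of [derivatives()]. The full model
#' started from `y1 = y2 = 0` must reproduce this trajectory exactly; the
#' reduction is used as an internal consistency oracle.
#'
#' The two-species system is integrated embedded in the model's
#' four-dimensional phase space (the two dormitive compartments pinned at
#' zero, with zero derivatives). The embedding changes no dynamics, but it
#' keeps the adaptive step controller's error norm — an RMS over state
#' components — identical to the full model's, so the reduction identity
#' holds to machine precision rather than merely to solver tolerance.
#'
#' @param params A `dormprey_params`.
#' @param initial Named numeric `(p, z)` initial densities.
#' @param t_span Numeric `(start, end)` days.
#' @param settings A [solver_settings()].
#' @return A `dormprey_trajectory` with columns `time`, `p`, `z`.
#' @export
rm_reference <- function(params = dormprey_params(),
                         initial = c(p = 2, z = 1),
                         t_span = c(0, 3000),
                         settings = solver_settings()) {
  params <- validate_params(params)
  if (length(initial) != 2 || any(initial < 0) || any(!is.finite(initial)))
    stop("initial must be a non-negative numeric vector (p, z)", call. = FALSE)
  names(initial) <- c("p", "z")
  stopifnot(length(t_span) == 2, t_span[2] > t_span[1], t_span[1] >= 0)
  times <- output_times(t_span, settings$output_dt)
  fn <- function(t, y, prm) {
    d <- rm_derivatives(y[c(1L, 4L)], prm)
    list(c(d[[1]], 0, 0, d[[2]]))
  }
  out <- deSolve::ode(y = c(initial[["p"]], 0, 0, initial[["z"]]),
                      times = times, func = fn,
                      parms = params, method = settings$method,
                      rtol = settings$rtol, atol = settings$atol)
  df <- new_trajectory(out, params, settings, initial, t_span)
  keep <- attributes(df)[c("params", "settings", "initial", "t_span",
                           "solver_stats")]
  df <- df[c("time", "p", "z")]
  for (nm in names(keep)) attr(df, nm) <- keep[[nm]]
  class(df) <- c("dormprey_trajectory", "data.frame")
  check_trajectory_finite(df, c("p", "z"))
}

#' @export
print.dormprey_trajectory <- function(x, ...) {
  sp <- setdiff(names(x), "time")
  cat(sprintf("<dormprey_trajectory> %d samples, t in [%g, %g], species: %s\n",
              nrow(x), x$time[1], x$time[nrow(x)], paste(sp, collapse = ", ")))
  fin <- x[nrow(x), sp, drop = FALSE]
  cat("  final state:",
      paste(sprintf("%s = %.6g", sp, unlist(fin)), collapse = ", "), "\n")
  invisible(x)
}

trajectory_species <- function(trajectory, species) {
  sp <- setdiff(names(trajectory), "time")
  if (!is.character(species) || length(species) != 1 || !(species %in% sp))
    stop("unknown species '", species, "'; available: ",
         paste(sp, collapse = ", "), call. = FALSE)
  trajectory[[species]]
}
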