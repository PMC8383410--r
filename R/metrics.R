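# Peak detection on a sampled series. Interior strict local maxima with a
# plateau-midpoint rule; optional quadratic refinement of time and value
# through the three samples around each discrete maximum, so peak times are
# resolved below the output sampling interval.
find_peaks_series <- function(times, values, prominence = 1e-6,
                              refine = TRUE) {
  n <- length(values)
  if (n < 3) return(data.frame(time = numeric(0), value = numeric(0)))
  pk_t <- numeric(0); pk_v <- numeric(0)
  i <- 2L
  while (i < n) {
    if (values[i] > values[i - 1L]) {
      j <- i
      while (j < n && values[j + 1L] == values[j]) j <- j + 1L
      if (j < n && values[j + 1L] < values[j]) {
        if (j > i) {                       # plateau: midpoint, no refinement
          pk_t <- c(pk_t, (times[i] + times[j]) / 2)
          pk_v <- c(pk_v, values[i])
        } else if (refine) {
          a <- values[i - 1L]; b <- values[i]; cc <- values[i + 1L]
          den <- a - 2 * b + cc
          if (den < 0) {
            off <- 0.5 * (a - cc) / den
            dt <- times[i + 1L] - times[i]
            pk_t <- c(pk_t, times[i] + off * dt)
            pk_v <- c(pk_v, b - 0.25 * (a - cc) * off)
          } else {
            pk_t <- c(pk_t, times[i]); pk_v <- c(pk_v, b)
          }
        } else {
          pk_t <- c(pk_t, times[i]); pk_v <- c(pk_v, values[i])
        }
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  keep <- pk_v >= prominence
  data.frame(time = pk_t[keep], value = pk_v[keep])
}

#' Locate cycle peaks of one species
#'
#' Returns the interior local maxima of a species' sampled trajectory:
#' samples strictly greater than both neighbours (plateaus count once, at
#' their midpoint). Endpoints are never peaks. Peaks below the prominence
#' floor — solver-scale ripple on near-extinct series — are dropped. Peak
#' times and values are refined by quadratic interpolation through the three
#' samples around each discrete maximum.
#'
#' @param trajectory A `dormprey_trajectory` (at least 3 samples).
#' @param species One of `"p"`, `"y1"`, `"y2"`, `"z"`.
#' @param window Optional `(start, end)` days restricting the search.
#' @param prominence Minimum peak density (mg L^-1); default 1e-6.
#' @param refine Quadratic time/value refinement (default `TRUE`).
#' @return A `peak_series`: data frame with columns `time`, `value` and a
#'   `species` attribute.
#' @export
find_peaks <- function(trajectory, species, window = NULL,
                       prominence = 1e-6, refine = TRUE) {
  v <- trajectory_species(trajectory, species)
  t <- trajectory$time
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; v <- v[keep]
  }
  if (length(t) < 3)
    stop("trajectory must have at least 3 samples", call. = FALSE)
  pk <- find_peaks_series(t, v, prominence = prominence, refine = refine)
  attr(pk, "species") <- species
  class(pk) <- c("peak_series", "data.frame")
  pk
}

#' Time of permanent decline below a density threshold
#'
#' First sample time from which the species' density stays below `threshold`
#' through the end of the trajectory. A species that later re-exceeds the
#' threshold — including one still above it at the final sample — has no
#' extinction time (`NA`). Extinction is diagnosed post hoc from the dense
#' trajectory; compartments are never zeroed during integration.
#'
#' @param trajectory A `dormprey_trajectory`.
#' @param species Species label.
#' @param threshold Extinction threshold (mg L^-1), strictly positive;
#'   default 1e-3, three orders of magnitude below the reference initial
#'   densities.
#' @return Extinction time in days, or `NA_real_` if the species persists.
#' @export
extinction_time <- function(trajectory, species, threshold = 1e-3) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0", call. = FALSE)
  v <- trajectory_species(trajectory, species)
  t <- trajectory$time
  above <- which(v >= threshold)
  if (length(above) == 0) return(as.numeric(t[1]))
  last_above <- above[length(above)]
  if (last_above == length(v)) return(NA_real_)
  as.numeric(t[last_above + 1L])
}

#' Reversal time of the prey competition
#'
#' The reversal time is the first time a cycle peak of the active form of
#' the dormitive prey (`y1`) exceeds the PA prey's peak density — the moment
#' the nominally disadvantaged prey overtakes. Peaks of `p` and `y1` are
#' extracted with [find_peaks()]; each `y1` peak is compared against the
#' most recent preceding `p` peak (after the PA prey's collapse this is its
#' last recorded peak). `y1` peaks occurring before the first `p` peak are
#' skipped. Returns `NA` if no `y1` peak ever exceeds the paired `p` peak —
#' e.g. when the PA prey keeps the advantage at low carrying capacity.
#'
#' @param trajectory A `dormprey_trajectory` covering the competition
#'   transient (an end time of at least 500 days is recommended).
#' @param prominence Peak prominence floor passed to [find_peaks()].
#' @return Reversal time in days, or `NA_real_`.
#' @export
reversal_time <- function(trajectory, prominence = 1e-6) {
  pk_p <- find_peaks(trajectory, "p", prominence = prominence)
  pk_y <- find_peaks(trajectory, "y1", prominence = prominence)
  if (nrow(pk_y) == 0 || nrow(pk_p) == 0) return(NA_real_)
  for (i in seq_len(nrow(pk_y))) {
    prev <- which(pk_p$time < pk_y$time[i])
    if (length(prev) == 0) next
    if (pk_y$value[i] > pk_p$value[max(prev)]) return(pk_y$time[i])
  }
  NA_real_
}

#' Classify the competition winner over a stable window
#'
#' Compares the maximum densities of the PA prey and the active form of the
#' dormitive prey over a late-time window (default days 2800-3000, after
#' transients have resolved into stable competition). The species with the
#' strictly larger window maximum wins, provided that maximum is at least
#' the extinction threshold; if both maxima are below threshold, or exactly
#' tied, the outcome is `"none"`.
#'
#' @param trajectory A `dormprey_trajectory` whose span covers `window`.
#' @param window `(start, end)` days; default `c(2800, 3000)`.
#' @param threshold Extinction threshold (mg L^-1), default 1e-3.
#' @return A `competition_outcome`: list with `winner` (`"PA"`,
#'   `"dormitive"` or `"none"`), `window`, `pa_max`, `y1_max`.
#' @export
classify_winner <- function(trajectory, window = c(2800, 3000),
                            threshold = 1e-3) {
  t <- trajectory$time
  if (window[1] < t[1] || window[2] > t[length(t)] || window[2] <= window[1])
    stop(sprintf("window [%g, %g] outside trajectory span [%g, %g]",
                 window[1], window[2], t[1], t[length(t)]), call. = FALSE)
  keep <- t >= window[1] & t <= window[2]
  pa_max <- max(trajectory$p[keep])
  y1_max <- max(trajectory$y1[keep])
  winner <- if (pa_max > y1_max && pa_max >= threshold) "PA"
            else if (y1_max > pa_max && y1_max >= threshold) "dormitive"
            else "none"
  structure(list(winner = winner, window = window,
                 pa_max = pa_max, y1_max = y1_max),
            class = "competition_outcome")
}

#' @export
print.competition_outcome <- function(x, ...) {
  cat(sprintf("<competition_outcome> winner: %s (window [%g, %g])\n",
              x$winner, x$window[1], x$window[2]))
  cat(sprintf("  max PA prey:            %.6g mg/L\n", x$pa_max))
  cat(sprintf("  max dormitive (active): %.6g mg/L\n", x$y1_max))
  invisible(x)
}

#' Reversal time as a function of carrying capacity
#'
#' Runs one integration per carrying capacity (identical initial state and
#' solver settings) and records the reversal time, tracing how enrichment
#' accelerates the dormitive prey's takeover.
#'
#' @param params Base `dormprey_params`; `K` is overridden per run.
#' @param K_values Positive carrying capacities (mg L^-1).
#' @param initial Initial state, default (2, 2, 0, 1).
#' @param t_span Integration span, default `c(0, 1000)` (the reversal is a
#'   transient-phase event).
#' @param settings A [solver_settings()].
#' @return Data frame with columns `K` and `T_w` (`NA` where no reversal
#'   occurs).
#' @export
reversal_curve <- function(params = dormprey_params(), K_values,
                           initial = initial_state(),
                           t_span = c(0, 1000),
                           settings = solver_settings()) {
  if (any(K_values <= 0)) stop("K_values must be positive", call. = FALSE)
  tw <- vapply(K_values, function(K) {
    traj <- integrate_model(update_params(params, K = K), initial,
                            t_span, settings)
    reversal_time(traj)
  }, numeric(1))
  data.frame(K = K_values, T_w = tw)
}
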