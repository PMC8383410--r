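#' Sweep axis specification
#'
#' One axis of a two-parameter sweep: a parameter name (or several names
#' tied together, all set to the same value — used e.g. to vary the two
#' active-prey foraging efficiencies jointly) and the ordered grid values.
#'
#' @param parameter Character vector of `dormprey_params` field names; more
#'   than one name ties the fields to a single axis.
#' @param values Finite numeric grid values.
#' @return An `axis_spec`.
#' @export
axis_spec <- function(parameter, values) {
  if (!is.character(parameter) || length(parameter) < 1)
    stop("parameter must be one or more field names", call. = FALSE)
  unknown <- setdiff(parameter, PARAM_NAMES)
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  values <- as.numeric(values)
  if (length(values) < 1 || anyNA(values) || any(!is.finite(values)))
    stop("axis values must be finite", call. = FALSE)
  structure(list(parameter = parameter, values = values,
                 label = paste(parameter, collapse = "+")),
            class = "axis_spec")
}

apply_axis <- function(params, axis, value) {
  ov <- as.list(rep(value, length(axis$parameter)))
  names(ov) <- axis$parameter
  do.call(update_params, c(list(params), ov))
}

#' Two-parameter sweep with winner classification
#'
#' For every cell of the `axis1` x `axis2` grid, overrides the two
#' parameters on `base`, re-validates, integrates the model from `initial`
#' to the end of `window`, and classifies the competition winner over
#' `window` with [classify_winner()]. Cells whose overridden parameter set
#' violates a joint constraint (e.g. `chi + phi > 1`, or a `constraint`
#' predicate supplied by the caller) are masked infeasible, not errors: the
#' grid keeps its full shape. Cells are mutually independent; evaluation
#' order cannot affect any cell's outcome.
#'
#' @param base Base `dormprey_params`.
#' @param axis1,axis2 [axis_spec()] objects over distinct parameters;
#'   `axis1` is the row (major) axis.
#' @param window Stable evaluation window, default `c(2800, 3000)`.
#' @param initial Initial state, default (2, 2, 0, 1).
#' @param threshold Extinction threshold for winner classification.
#' @param settings A [solver_settings()].
#' @param constraint Optional `function(params) -> logical`; cells where it
#'   returns `FALSE` are masked infeasible.
#' @return A `sweep_grid`: list with the axes and a cell list (axis1-major)
#'   of `competition_outcome`s (`NULL` where infeasible), plus a logical
#'   `feasible` matrix. Use [as.data.frame()] for the long format.
#' @export
run_grid <- function(base = dormprey_params(), axis1, axis2,
                     window = c(2800, 3000),
                     initial = initial_state(),
                     threshold = 1e-3,
                     settings = solver_settings(),
                     constraint = NULL) {
  stopifnot(inherits(axis1, "axis_spec"), inherits(axis2, "axis_spec"))
  if (length(intersect(axis1$parameter, axis2$parameter)))
    stop("axis parameters must be distinct", call. = FALSE)
  base <- validate_params(base)
  n1 <- length(axis1$values); n2 <- length(axis2$values)
  feasible <- matrix(TRUE, n1, n2)
  cells <- vector("list", n1 * n2)

  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      prm <- try(apply_axis(apply_axis(base, axis1, axis1$values[i]),
                            axis2, axis2$values[j]), silent = TRUE)
      ok <- !inherits(prm, "try-error") &&
        (is.null(constraint) || isTRUE(constraint(prm)))
      idx <- (i - 1L) * n2 + j
      if (!ok) {
        feasible[i, j] <- FALSE
        next
      }
      traj <- integrate_model(prm, initial, c(0, window[2]), settings)
      cells[[idx]] <- classify_winner(traj, window, threshold)
    }
  }
  structure(list(axis1 = axis1, axis2 = axis2, window = window,
                 base = base, threshold = threshold,
                 feasible = feasible, cells = cells),
            class = "sweep_grid")
}

#' @export
print.sweep_grid <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<sweep_grid> %s x %s (%d x %d), window [%g, %g]\n",
              x$axis1$label, x$axis2$label,
              length(x$axis1$values), length(x$axis2$values),
              x$window[1], x$window[2]))
  print(table(winner = df$winner[df$feasible]))
  inf <- sum(!df$feasible)
  if (inf) cat(sprintf("  %d infeasible cell(s)\n", inf))
  invisible(x)
}

#' Long-format view of a sweep grid
#'
#' @param x A `sweep_grid`.
#' @param ... Unused.
#' @return Data frame with columns `axis1_value`, `axis2_value`, `winner`,
#'   `pa_max`, `y1_max`, `feasible`; infeasible cells carry `NA` outcomes.
#' @export
as.data.frame.sweep_grid <- function(x, ...) {
  n1 <- length(x$axis1$values); n2 <- length(x$axis2$values)
  grid <- expand.grid(axis2_value = x$axis2$values,
                      axis1_value = x$axis1$values)[, 2:1]
  winner <- rep(NA_character_, n1 * n2)
  pa_max <- y1_max <- rep(NA_real_, n1 * n2)
  for (k in seq_along(x$cells)) {
    cell <- x$cells[[k]]
    if (!is.null(cell)) {
      winner[k] <- cell$winner
      pa_max[k] <- cell$pa_max
      y1_max[k] <- cell$y1_max
    }
  }
  out <- cbind(grid, winner = winner, pa_max = pa_max, y1_max = y1_max,
               feasible = as.vector(t(x$feasible)))
  names(out)[1:2] <- c("axis1_value", "axis2_value")
  rownames(out) <- NULL
  out
}

#' Winner-label matrix of a sweep grid
#'
#' @param grid A `sweep_grid`.
#' @return Character matrix (axis1 rows x axis2 columns) of winner labels;
#'   `NA` where infeasible.
#' @export
winner_matrix <- function(grid) {
  df <- as.data.frame(grid)
  matrix(df$winner, nrow = length(grid$axis1$values),
         ncol = length(grid$axis2$values), byrow = TRUE,
         dimnames = list(format(grid$axis1$values, trim = TRUE),
                         format(grid$axis2$values, trim = TRUE)))
}

# Default panel axis ranges. Chosen to bracket the reference parameter
# values and the regime shifts the model exhibits; all configurable through
# run_grid() directly.
PANEL_DEFS <- list(
  A = list(a1 = list("K", c(5, 25)),      a2 = list("alpha", c(0, 1))),
  B = list(a1 = list("K", c(5, 25)),      a2 = list("d_z", c(0.05, 0.5))),
  C = list(a1 = list("chi", c(0, 1)),     a2 = list("phi", c(0, 1))),
  D = list(a1 = list("eta", c(0.2, 3)),   a2 = list("sigma", c(0.01, 1))),
  E = list(a1 = list(c("k_p", "k_y1"), c(0.1, 0.9)),
           a2 = list("k_y2", c(0.1, 0.9))),
  F = list(a1 = list(c("c_p", "c_y1"), c(0.2, 2)),
           a2 = list("c_y2", c(0.2, 2)))
)

#' The six canonical parameter-space panels
#'
#' Runs the six paired parameter scans that map where each prey type wins:
#' (A) carrying capacity `K` vs dormancy termination rate `alpha`;
#' (B) `K` vs predator death rate `d_z`;
#' (C) switching lower bound `chi` vs range `phi`, with cells violating
#' `chi + phi <= 1` masked infeasible;
#' (D) switching threshold `eta` vs width `sigma`;
#' (E) active-prey growth efficiencies `k_p = k_y1` (tied axis) vs `k_y2`;
#' (F) active-prey foraging efficiencies `c_p = c_y1` (tied axis) vs
#' `c_y2`, with cells where the dormant form is easier to catch than the
#' active forms (`c_y2 > min(c_p, c_y1)`) masked infeasible.
#'
#' @param resolution Grid points per axis (>= 5); default 21.
#' @param window Stable evaluation window, default `c(2800, 3000)`.
#' @param panels Subset of `c("A","B","C","D","E","F")`.
#' @param base Base parameters.
#' @param settings A [solver_settings()].
#' @param tie_active Untie the E/F joint axes (set `FALSE` to vary only
#'   `k_p` / `c_p`, leaving `k_y1` / `c_y1` at their base values).
#' @return Named list of `sweep_grid`s.
#' @export
figure3_panels <- function(resolution = 21, window = c(2800, 3000),
                           panels = names(PANEL_DEFS),
                           base = dormprey_params(),
                           settings = solver_settings(),
                           tie_active = TRUE) {
  if (resolution < 5) stop("resolution must be >= 5", call. = FALSE)
  panels <- match.arg(panels, names(PANEL_DEFS), several.ok = TRUE)
  out <- list()
  for (pn in panels) {
    def <- PANEL_DEFS[[pn]]
    mk <- function(d) {
      par <- d[[1]]
      if (!tie_active && length(par) > 1) par <- par[1]
      axis_spec(par, seq(d[[2]][1], d[[2]][2], length.out = resolution))
    }
    constraint <- if (pn == "F") {
      function(prm) prm$c_y2 <= min(prm$c_p, prm$c_y1)
    } else NULL
    out[[pn]] <- run_grid(base, mk(def$a1), mk(def$a2), window = window,
                          settings = settings, constraint = constraint)
  }
  out
}
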