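#' @keywords internal
# Canonical field order; also the order in which values are passed to the
# compiled right-hand side, so never reorder without touching src/.
PARAM_NAMES <- c(
  "r_p", "r_y", "K", "d_z", "alpha",
  "k_p", "k_y1", "k_y2",
  "c_p", "c_y1", "c_y2",
  "h_p", "h_y1", "h_y2",
  "eta", "sigma", "chi", "phi"
)

STATE_NAMES <- c("p", "y1", "y2", "z")

#' Model parameter set
#'
#' Constructs the full parameter record of the dormancy predator-prey model.
#' The defaults are the published reference parameterisation of the model:
#' a perennially active (PA) prey with growth rate `r_p`, a dormitive prey
#' with growth rate `r_y` whose reproduction is split between active and
#' dormant offspring by the switching function [dormancy_switch()], a shared
#' carrying capacity `K` felt by the two active prey compartments, and a
#' predator taking all three prey compartments through Holling type-II
#' responses.
#'
#' @param r_p PA-prey maximum growth rate (day^-1).
#' @param r_y Dormitive-prey maximum growth rate (day^-1).
#' @param K Prey carrying capacity (mg L^-1), shared by `p` and `y1` only;
#'   the dormant form does not contribute to crowding.
#' @param d_z Predator death rate (day^-1).
#' @param alpha Dormancy termination rate (day^-1): per-capita rate at which
#'   dormant individuals re-activate.
#' @param k_p,k_y1,k_y2 Predator growth efficiencies from each prey
#'   compartment (dimensionless).
#' @param c_p,c_y1,c_y2 Predator foraging efficiencies (day^-1 mg^-1 L).
#' @param h_p,h_y1,h_y2 Predator handling times (days).
#' @param eta Switching threshold (mg L^-1): predator density at which the
#'   switching function sits at its midpoint.
#' @param sigma Switching width (mg L^-1): smaller values give sharper
#'   switching.
#' @param chi Switching lower bound (dimensionless).
#' @param phi Switching range (dimensionless); `chi + phi` is the upper
#'   bound of the active-allocation fraction and must not exceed 1.
#'
#' @return A validated object of class `dormprey_params` (a named list with
#'   one numeric scalar per field).
#' @seealso [validate_params()], [scenario_preset()], [derivatives()]
#' @examples
#' p <- dormprey_params()            # reference values
#' p13 <- dormprey_params(K = 13)    # enriched environment
#' @export
dormprey_params <- function(r_p = 0.55, r_y = 0.5, K = 11, d_z = 0.2,
                            alpha = 0.05,
                            k_p = 0.5, k_y1 = 0.5, k_y2 = 0.25,
                            c_p = 1, c_y1 = 1, c_y2 = 0.4,
                            h_p = 0.5, h_y1 = 0.5, h_y2 = 0.5,
                            eta = 1, sigma = 0.1, chi = 0.2, phi = 0.75) {
  prm <- mget(PARAM_NAMES, environment())
  prm <- lapply(prm, as.numeric)
  class(prm) <- "dormprey_params"
  validate_params(prm)
}

#' Validate a parameter set
#'
#' Checks every invariant the model places on its parameters: all rates and
#' capacities non-negative, `K`, `sigma` and the handling times strictly
#' positive, and the switching-function bound `0 <= chi <= chi + phi <= 1`
#' (required so the active-allocation fraction stays in `[0, 1]`).
#'
#' @param params A `dormprey_params` object (or a named list coercible to
#'   one via [as_dormprey_params()]).
#' @return The parameter set, unchanged, if valid; otherwise an error naming
#'   every violated constraint.
#' @export
validate_params <- function(params) {
  params <- as_dormprey_params(params)
  v <- unlist(params[PARAM_NAMES])
  bad <- character(0)
  if (anyNA(v) || any(!is.finite(v))) {
    bad <- c(bad, sprintf("non-finite value in: %s",
                          paste(PARAM_NAMES[!is.finite(v)], collapse = ", ")))
  } else {
    neg <- PARAM_NAMES[v < 0]
    if (length(neg))
      bad <- c(bad, sprintf("negative value not allowed: %s",
                            paste(neg, collapse = ", ")))
    if (v[["K"]] <= 0) bad <- c(bad, "K must be > 0")
    if (v[["sigma"]] <= 0)
      bad <- c(bad, "sigma must be > 0 (zero width makes the switching function singular)")
    hpos <- c("h_p", "h_y1", "h_y2")
    hbad <- hpos[v[hpos] <= 0]
    if (length(hbad))
      bad <- c(bad, sprintf("handling time must be > 0: %s",
                            paste(hbad, collapse = ", ")))
    if (v[["chi"]] + v[["phi"]] > 1)
      bad <- c(bad, sprintf(
        "chi + phi = %g exceeds 1; the switching function requires 0 <= chi <= chi + phi <= 1",
        v[["chi"]] + v[["phi"]]))
  }
  if (length(bad))
    stop("invalid parameter set:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  params
}

#' Coerce a named list or vector to a parameter set
#'
#' Fills unspecified fields with the defaults of [dormprey_params()].
#' Unknown field names are an error, so typos in sweep or config files are
#' caught instead of silently ignored.
#'
#' @param x A `dormprey_params`, named list, or named numeric vector.
#' @return A `dormprey_params` object (not re-validated; see
#'   [validate_params()]).
#' @export
as_dormprey_params <- function(x) {
  if (inherits(x, "dormprey_params")) return(x)
  if (is.numeric(x)) x <- as.list(x)
  if (!is.list(x) || is.null(names(x)) || any(names(x) == ""))
    stop("parameters must be a named list or named numeric vector", call. = FALSE)
  unknown <- setdiff(names(x), PARAM_NAMES)
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  prm <- formals(dormprey_params)
  prm <- lapply(prm, eval, envir = baseenv())
  prm[names(x)] <- lapply(x, as.numeric)
  prm <- prm[PARAM_NAMES]
  class(prm) <- "dormprey_params"
  prm
}

#' Override fields of a parameter set
#'
#' @param params Base `dormprey_params`.
#' @param ... Named scalar overrides, e.g. `K = 13`.
#' @return A validated `dormprey_params`.
#' @export
update_params <- function(params, ...) {
  params <- as_dormprey_params(params)
  ov <- list(...)
  if (length(ov) == 0) return(params)
  unknown <- setdiff(names(ov), PARAM_NAMES)
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params[names(ov)] <- lapply(ov, as.numeric)
  validate_params(params)
}

#' @export
print.dormprey_params <- function(x, ...) {
  cat("<dormprey_params>\n")
  v <- unlist(x[PARAM_NAMES])
  cat(paste0("  ", format(PARAM_NAMES, width = 6), " = ",
             format(v, digits = 6, trim = TRUE), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
as.list.dormprey_params <- function(x, ...) {
  out <- unclass(x)
  out[PARAM_NAMES]
}

#' Initial state vector
#'
#' @param p,y1,y2,z Initial densities (mg L^-1) of the PA prey, the active
#'   and dormant forms of the dormitive prey, and the predator. Defaults are
#'   the reference initial condition (2, 2, 0, 1).
#' @return Named numeric vector with entries `p`, `y1`, `y2`, `z`.
#' @export
initial_state <- function(p = 2, y1 = 2, y2 = 0, z = 1) {
  s <- c(p = as.numeric(p), y1 = as.numeric(y1),
         y2 = as.numeric(y2), z = as.numeric(z))
  validate_state(s)
}

validate_state <- function(state) {
  if (is.list(state)) state <- unlist(state)
  if (!is.numeric(state) || length(state) != 4)
    stop("state must be a numeric vector of length 4 (p, y1, y2, z)",
         call. = FALSE)
  storage.mode(state) <- "double"
  if (is.null(names(state)) || all(names(state) == "")) {
    names(state) <- STATE_NAMES
  } else if (!identical(sort(names(state)), sort(STATE_NAMES))) {
    stop("state names must be p, y1, y2, z", call. = FALSE)
  }
  state <- state[STATE_NAMES]
  if (anyNA(state) || any(!is.finite(state)))
    stop("state densities must be finite", call. = FALSE)
  if (any(state < 0))
    stop("state densities must be >= 0 on construction", call. = FALSE)
  state
}

# ---- scenario presets -------------------------------------------------------

PRESETS <- list(
  fig1a = list(
    params = list(alpha = 1, chi = 1, phi = 0),
    initial = c(p = 2, y1 = 2, y2 = 0, z = 1), t_span = c(0, 200),
    notes = "active form of the dormitive prey alone vs the PA prey; mu(z) pinned at 1 so no dormant offspring are produced"),
  fig1b = list(
    params = list(alpha = 0, chi = 0, phi = 0),
    initial = c(p = 2, y1 = 0, y2 = 2, z = 1), t_span = c(0, 200),
    notes = "dormant form alone vs the PA prey; with mu = 0 and alpha = 0 the dormant pool can only decay"),
  fig1c = list(
    params = list(),
    initial = c(p = 2, y1 = 2, y2 = 0, z = 1), t_span = c(0, 3000),
    notes = "full competition at reference parameters (K = 11); the dormitive prey overtakes after the PA prey collapses"),
  fig2a = list(
    params = list(K = 13),
    initial = c(p = 2, y1 = 2, y2 = 0, z = 1), t_span = c(0, 3000),
    notes = "enriched environment, K = 13; earlier reversal"),
  fig2b = list(
    params = list(K = 20),
    initial = c(p = 2, y1 = 2, y2 = 0, z = 1), t_span = c(0, 3000),
    notes = "strongly enriched environment, K = 20; earliest reversal"),
  fig2c = list(
    params = list(K = 9),
    initial = c(p = 2, y1 = 2, y2 = 0, z = 1), t_span = c(0, 3000),
    notes = "poor environment, K = 9; the PA prey keeps the advantage and persists")
)

#' List scenario presets
#'
#' @return Character vector of preset names understood by
#'   [scenario_preset()].
#' @export
scenario_presets <- function() names(PRESETS)

#' Retrieve a scenario preset
#'
#' Presets bundle the parameter overrides, initial state and time span of
#' the model's canonical competition scenarios: single-form competitions
#' (`fig1a`, `fig1b`), the full competition at the reference carrying
#' capacity (`fig1c`), and the enriched / impoverished variants
#' (`fig2a` K = 13, `fig2b` K = 20, `fig2c` K = 9).
#'
#' @param name Preset name; see [scenario_presets()].
#' @return List with elements `name`, `params` (full `dormprey_params`),
#'   `initial`, `t_span`, `notes`.
#' @export
scenario_preset <- function(name) {
  if (!is.character(name) || length(name) != 1 || !(name %in% names(PRESETS)))
    stop("unknown preset; available: ", paste(names(PRESETS), collapse = ", "),
         call. = FALSE)
  pr <- PRESETS[[name]]
  list(name = name,
       params = do.call(update_params, c(list(dormprey_params()), pr$params)),
       initial = validate_state(pr$initial),
       t_span = pr$t_span,
       notes = pr$notes)
}
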