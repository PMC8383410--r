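#' Holling type-II functional response
#'
#' Per-predator consumption rate of a prey compartment,
#' `f(q) = c_q q / (1 + c_q h_q q)`. The rate grows linearly (`c_q q`) for
#' scarce prey and saturates at `1 / h_q` for abundant prey.
#'
#' @param q Prey density (mg L^-1), vectorised.
#' @param c_q Foraging efficiency (day^-1 mg^-1 L).
#' @param h_q Handling time (days), strictly positive.
#' @return Predation rate (day^-1), same length as `q`.
#' @examples
#' holling_response(2, 1, 0.5)   # 1
#' holling_response(1e6, 1, 0.5) # ~ 2 = 1 / h_q
#' @export
holling_response <- function(q, c_q, h_q) {
  if (any(q < 0)) stop("prey density q must be >= 0", call. = FALSE)
  if (c_q < 0) stop("foraging efficiency c_q must be >= 0", call. = FALSE)
  if (h_q <= 0) stop("handling time h_q must be > 0", call. = FALSE)
  c_q * q / (1 + c_q * h_q * q)
}

#' Dormancy switching function
#'
#' Fraction of dormitive-prey reproduction allocated to active offspring,
#' `mu(z) = chi + phi / (1 + exp((z - eta) / sigma))`: a decreasing sigmoid
#' of predator density that allocates mostly active offspring when predators
#' are scarce (`mu -> chi + phi`) and mostly dormant offspring when they are
#' abundant (`mu -> chi`). The exponent is clamped at +/- 700 so extreme
#' predator densities return the exact asymptote instead of overflowing.
#'
#' @param z Predator density (mg L^-1), vectorised.
#' @param params A `dormprey_params` (only `eta`, `sigma`, `chi`, `phi` are
#'   used).
#' @return Allocation fraction in `[chi, chi + phi]`, same length as `z`.
#' @examples
#' dormancy_switch(1, dormprey_params())    # midpoint: chi + phi / 2
#' dormancy_switch(1e6, dormprey_params())  # chi
#' @export
dormancy_switch <- function(z, params) {
  params <- validate_params(params)
  if (any(z < 0)) stop("predator density z must be >= 0", call. = FALSE)
  ex <- (z - params$eta) / params$sigma
  ex <- pmin(pmax(ex, -700), 700)
  params$chi + params$phi / (1 + exp(ex))
}

#' Model right-hand side
#'
#' Evaluates the four coupled rate equations of the model at a state
#' `(p, y1, y2, z)`:
#' \itemize{
#'   \item PA prey: logistic growth `r_p (1 - (p + y1)/K) p` minus predation
#'     `f_p(p) z`.
#'   \item Active dormitive form: the fraction `mu(z)` of its logistic
#'     reproduction, plus re-activation `alpha y2`, minus predation.
#'   \item Dormant form: the complementary fraction `1 - mu(z)` of the
#'     active form's reproduction, minus re-activation and predation. The
#'     dormant form is sterile and exerts no crowding.
#'   \item Predator: growth-efficiency-weighted intake from the three prey
#'     compartments minus constant mortality `d_z z`.
#' }
#' Densities enter the predation terms and the crowding term clamped at
#' zero, so tiny negative excursions from an adaptive solver (magnitude
#' below the absolute tolerance) cannot destabilise the right-hand side;
#' the state itself is never modified.
#'
#' @param state Named numeric vector `(p, y1, y2, z)`; small negative
#'   entries (solver undershoot) are tolerated.
#' @param params A `dormprey_params`.
#' @return Named numeric vector of time derivatives (mg L^-1 day^-1).
#' @examples
#' derivatives(initial_state(), dormprey_params())
#' @export
derivatives <- function(state, params) {
  params <- validate_params(params)
  if (is.null(names(state))) names(state) <- STATE_NAMES
  p <- state[["p"]]; y1 <- state[["y1"]]; y2 <- state[["y2"]]; z <- state[["z"]]

  mu <- dormancy_switch(max(z, 0), params)
  crowd <- 1 - (max(p, 0) + max(y1, 0)) / params$K
  f_p  <- holling_response(max(p, 0),  params$c_p,  params$h_p)
  f_y1 <- holling_response(max(y1, 0), params$c_y1, params$h_y1)
  f_y2 <- holling_response(max(y2, 0), params$c_y2, params$h_y2)

  c(p  = params$r_p * crowd * p - f_p * z,
    y1 = params$r_y * crowd * mu * y1 + params$alpha * y2 - f_y1 * z,
    y2 = params$r_y * crowd * (1 - mu) * y1 - params$alpha * y2 - f_y2 * z,
    z  = params$k_p * f_p * z + params$k_y1 * f_y1 * z +
         params$k_y2 * f_y2 * z - params$d_z * z)
}

# Two-species Rosenzweig-MacArthur right-hand side (PA prey + predator only).
# Kept deliberately separate from derivatives(): it is the reduction oracle
# for the y1 = y2 = 0 limit of the full model.
rm_derivatives <- function(state, params) {
  p <- state[[1]]; z <- state[[2]]
  f_p <- holling_response(max(p, 0), params$c_p, params$h_p)
  c(p = params$r_p * (1 - max(p, 0) / params$K) * p - f_p * z,
    z = params$k_p * f_p * z - params$d_z * z)
}

#' Predator-nullcline prey density of the two-species reduction
#'
#' Solves `k_p f_p(p) = d_z` for the prey density at which predator growth
#' balances mortality in the Rosenzweig-MacArthur reduction (`y1 = y2 = 0`):
#' `p* = d_z / (c_p (k_p - h_p d_z))`. At the reference parameters this is
#' 0.5 mg L^-1.
#'
#' @param params A `dormprey_params`.
#' @return Equilibrium prey density (mg L^-1); `Inf` if the predator cannot
#'   persist (`k_p <= h_p d_z`).
#' @export
rm_prey_nullcline <- function(params) {
  params <- validate_params(params)
  denom <- params$c_p * (params$k_p - params$h_p * params$d_z)
  if (denom <= 0) return(Inf)
  params$d_z / denom
}
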