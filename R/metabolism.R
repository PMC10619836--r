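#' Mass-dependent energy budget
#'
#' Agents are endotherms whose daily meat requirement follows the all-bird
#' field-metabolic-rate allometry, expressed directly in kg of wet meat and
#' anchored so that a 2,000 kg agent needs 29 kg/day:
#' `N(M) = 29 * (M / 2000)^0.681`. Body "energy" is tracked as mass in kg of
#' meat equivalent: each day an agent's mass changes by intake minus
#' requirement, and it dies of starvation once mass drops below a fixed
#' floor of 92% of its initialization mass (1,840 kg by default).
#'
#' @name metabolism
NULL

#' Daily meat requirement
#'
#' @param mass body mass in kg (vectorised), must be positive.
#' @param anchor_mass,anchor_req calibration point: an `anchor_mass` kg agent
#'   needs `anchor_req` kg meat/day.
#' @param exponent allometric exponent (all-bird FMR scaling).
#' @return kg of meat per day.
#' @examples
#' daily_meat_requirement(2000)  # 29
#' daily_meat_requirement(4000)  # 46.5
#' @export
daily_meat_requirement <- function(mass, anchor_mass = 2000,
                                   anchor_req = 29, exponent = 0.681) {
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("mass must be positive and finite")
  }
  anchor_req * (mass / anchor_mass)^exponent
}

#' One day of the body-mass ledger
#'
#' The agent feeds first, then pays its requirement computed from the
#' pre-update mass: `mass' = mass + consumed - N(mass)`. Mass may exceed the
#' initialization mass without bound (fat storage); growth is limited
#' dynamically because the requirement rises with mass.
#'
#' @param mass current body mass, kg.
#' @param consumed kg of meat eaten today (non-negative).
#' @param ... passed on to [daily_meat_requirement()].
#' @return updated mass, kg.
#' @export
apply_daily_budget <- function(mass, consumed = 0, ...) {
  if (any(consumed < 0)) stop("consumed must be non-negative")
  mass + consumed - daily_meat_requirement(mass, ...)
}

#' Starvation test
#'
#' Death occurs strictly below the floor ("dropped below"), which stays
#' fixed at `floor_frac` of the initialization mass even after growth.
#'
#' @param mass current body mass, kg.
#' @param birth_mass initialization mass, kg.
#' @param floor_frac floor as a fraction of `birth_mass`.
#' @return logical.
#' @export
is_starved <- function(mass, birth_mass = 2000, floor_frac = 0.92) {
  mass < floor_frac * birth_mass
}

#' Equilibrium mass for a sustained intake
#'
#' Inverts the requirement allometry: the mass at which a constant daily
#' intake `t` exactly balances the requirement, `M* = 2000 * (t/29)^(1/e)`.
#' An always-fed agent's mass converges monotonically to this value.
#'
#' @param intake sustained daily intake, kg meat/day.
#' @inheritParams daily_meat_requirement
#' @return equilibrium body mass, kg.
#' @export
equilibrium_mass <- function(intake, anchor_mass = 2000,
                             anchor_req = 29, exponent = 0.681) {
  anchor_mass * (intake / anchor_req)^(1 / exponent)
}
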