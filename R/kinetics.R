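#' Activation and deactivation rates of short-tailed AMPA subunits
#'
#' The reaction `R_S + NSF <-> R'_S` runs with state-dependent rate
#' "constants": the forward (activation) rate \eqn{k_0} grows with the
#' concentration of activated subunits \eqn{[R'_S]} because activated
#' homomers promote further activation, and the backward (deactivation)
#' rate \eqn{k_4} grows with the nonactivated subunit concentration
#' \eqn{[R_S]} because nonactivated heteromers promote deactivation.  This
#' pair of competing self-excitations is the double positive feedback loop
#' that makes the core system multistable.
#'
#' @param RpS,RS Nonnegative concentrations of activated (`RpS`) or
#'   nonactivated (`RS`) short-tailed subunits (vectorised).
#' @param curve A `synplast_scurve`; see [s_curve()] and [param_curves()].
#' @return Rate values between the two plateaus of `curve`.
#' @seealso [core_rhs()], [dimer_pools()]
#' @export
k0_rate <- function(RpS, curve) scurve_value(curve, RpS)

#' @rdname k0_rate
#' @export
k4_rate <- function(RS, curve) scurve_value(curve, RS)

#' Quasi-steady-state dimer pools
#'
#' The polymerisation reactions `2 R'_S <-> R'_S R'_S` (homomer) and
#' `R_S + R_L <-> R_S R_L` (heteromer) are fast and reversible; their pools
#' are carried algebraically at quasi-steady state:
#' \deqn{[R'_S R'_S] = (k_1/k_2)\,[R'_S]^2, \qquad
#'       [R_S R_L] = (k_5/k_6)\,[R_S]\,[R_L].}
#' The feedback of the dimers on the activation kinetics is already folded
#' into the S-curves \eqn{k_0} and \eqn{k_4}; the explicit pools are used
#' by the membrane trafficking layer only.
#'
#' @param RS,RpS Nonnegative concentrations.
#' @param params A [synplast_params()] set.
#' @return A named list with components `homomer` and `heteromer`.
#' @examples
#' dimer_pools(RS = 2, RpS = 0.5, params = synplast_params())
#' @export
dimer_pools <- function(RS, RpS, params) {
  if (any(RS < 0) || any(RpS < 0)) {
    stop("dimer_pools(): concentrations must be nonnegative", call. = FALSE)
  }
  list(
    homomer   = (params$k1 / params$k2) * RpS^2,
    heteromer = (params$k5 / params$k6) * RS * params$R_L
  )
}

#' Right-hand side of the core activation system
#'
#' Time derivatives of the three cytosolic species, with the interaction
#' term \eqn{I = k_0([R'_S])\,[R_S][NSF] - k_4([R_S])\,[R'_S]} entering all
#' three equations:
#' \deqn{[\dot{NSF}] = p_{NSF} - z_{NSF}[NSF] - I}
#' \deqn{[\dot{R}_S] = p_{R_S} - z_{R_S}[R_S] - I}
#' \deqn{[\dot{R}'_S] = -z_{R'_S}[R'_S] + I}
#' Because the same \eqn{I} appears in every equation, the combinations
#' `dNSF - dRS` and `dRS + dRpS` are free of the nonlinearity; this
#' conservation structure underlies the reduction of the stationary problem
#' to a single scalar equation (see [stationary_residual()]).
#'
#' @param state Named numeric vector with components `NSF`, `RS`, `RpS`.
#' @param p_NSF_eff,p_RS_eff Effective (cascade-modulated) production
#'   rates, nonnegative.
#' @param params A [synplast_params()] set.
#' @param curves Optional precomputed [param_curves()] (an optimisation for
#'   tight loops).
#' @return Named numeric vector of derivatives (`NSF`, `RS`, `RpS`).
#' @export
core_rhs <- function(state, p_NSF_eff, p_RS_eff, params,
                     curves = param_curves(params)) {
  NSF <- state[["NSF"]]; RS <- state[["RS"]]; RpS <- state[["RpS"]]
  # rate laws are defined on nonnegative concentrations; clamp the tiny
  # negative excursions an adaptive integrator can produce
  I <- scurve_value(curves$k0, max(RpS, 0)) * RS * NSF -
    scurve_value(curves$k4, max(RS, 0)) * RpS
  c(
    NSF = p_NSF_eff - params$z_NSF * NSF - I,
    RS  = p_RS_eff  - params$z_RS  * RS  - I,
    RpS = -params$z_RpS * RpS + I
  )
}

#' Jacobian of the core activation system
#'
#' Analytic 3x3 Jacobian of [core_rhs()] with respect to
#' `(NSF, RS, RpS)`, used for linear stability classification of
#' stationary points.
#'
#' @inheritParams core_rhs
#' @return A 3x3 matrix with rows/columns ordered `NSF`, `RS`, `RpS`.
#' @keywords internal
core_jacobian <- function(state, params, curves = param_curves(params)) {
  NSF <- state[["NSF"]]; RS <- state[["RS"]]; RpS <- max(state[["RpS"]], 0)
  RS <- max(RS, 0)
  k0  <- scurve_value(curves$k0, RpS)
  k4  <- scurve_value(curves$k4, RS)
  dk0 <- scurve_slope(curves$k0, RpS)
  dk4 <- scurve_slope(curves$k4, RS)
  dI_dNSF <- k0 * RS
  dI_dRS  <- k0 * NSF - dk4 * RpS
  dI_dRpS <- dk0 * RS * NSF - k4
  matrix(c(
    -params$z_NSF - dI_dNSF, -dI_dRS,                  -dI_dRpS,
    -dI_dNSF,                -params$z_RS - dI_dRS,    -dI_dRpS,
    dI_dNSF,                 dI_dRS,                   -params$z_RpS + dI_dRpS
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("NSF", "RS", "RpS"), c("NSF", "RS", "RpS")))
}
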