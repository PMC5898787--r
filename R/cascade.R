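#' Corticosteroid receptor occupancy
#'
#' Fractional occupancy of the mineralocorticoid (MR) and glucocorticoid
#' (GR) receptors at cortisol concentration `C`, by Michaelis--Menten
#' saturation:
#' \deqn{[MR] = \frac{C}{C + M_{MR}}, \qquad [GR] = \frac{C}{C + M_{GR}}.}
#' With the default constants (`M_MR = 1e-4`, `M_GR = 5`) MR is essentially
#' saturated at any physiological cortisol level while GR occupancy only
#' becomes substantial under stress -- the classical high/low affinity
#' division of labour between the two receptors.
#'
#' @param C Nonnegative cortisol concentration (vectorised).
#' @param params A [synplast_params()] set.
#' @return A list with components `MR` and `GR`, both in `[0, 1)` and with
#'   `MR >= GR` for every positive `C`.
#' @examples
#' receptor_occupancy(5, synplast_params())$GR  # half-saturated GR
#' @export
receptor_occupancy <- function(C, params) {
  if (any(C < 0)) {
    stop("receptor_occupancy(): cortisol concentration must be nonnegative",
         call. = FALSE)
  }
  list(MR = C / (C + params$M_MR), GR = C / (C + params$M_GR))
}

#' Receptor expression rates under MR/GR control
#'
#' Production rates of the two BDNF receptors given the corticosteroid
#' receptor occupancies.  MR promotes TrkB expression, GR represses it and
#' promotes p75 expression; the simplest functional forms realising this
#' control are
#' \deqn{\mathrm{TrkB\ production} = p_{TrkB}\, MR\,(1 - GR), \qquad
#'       \mathrm{p75\ production} = p_{p75}\, GR.}
#' Because MR saturates at low cortisol while GR saturation requires high
#' cortisol, steady-state TrkB expression is bell-shaped in cortisol:
#' maximal at low (normal) levels, low both without cortisol and under
#' stress.
#'
#' @param MR,GR Occupancy fractions in `[0, 1]`.
#' @param params A [synplast_params()] set.
#' @return A list with components `trkb_production` and `p75_production`.
#' @export
receptor_expression_rates <- function(MR, GR, params) {
  list(
    trkb_production = params$p_TrkB_expr * MR * (1 - GR),
    p75_production  = params$p_p75_expr * GR
  )
}

#' Cascade-modulated protein production rates
#'
#' The modulation variable `a` integrates the balance of TrkB versus p75
#' signalling; it shifts the ribosomal production rates of NSF and
#' \eqn{R_S} linearly, with the NSF channel the more sensitive one
#' (`u_NSF = 3` against `u_RS = 1`), and production clips at zero:
#' \deqn{p_{NSF}^{eff} = \max(0,\; p_{NSF} + u_{NSF}\,a), \qquad
#'       p_{R_S}^{eff} = \max(0,\; p_{R_S} + u_{R_S}\,a).}
#'
#' @param a Modulation level (may be negative).
#' @param base_p_NSF,base_p_RS Baseline production rates (>= 0).
#' @param params A [synplast_params()] set.
#' @return A list with components `p_NSF_eff` and `p_RS_eff`.
#' @export
effective_production <- function(a, base_p_NSF, base_p_RS, params) {
  list(
    p_NSF_eff = pmax(0, base_p_NSF + params$u_NSF * a),
    p_RS_eff  = pmax(0, base_p_RS + params$u_RS * a)
  )
}

#' Right-hand side of the stimulation/cortisol cascade
#'
#' Time derivatives of the upstream signalling layer that converts the
#' presynaptic signal `s(t)`, the pre/post coincidence gain `sigma` and the
#' cortisol level `C` into the production-modulation variable `a`:
#'
#' * CaMKII is driven by coincident activity (its activation is
#'   Ca2+/calmodulin-dependent downstream of the NMDA receptor):
#'   `d CaMKII = b_CaMKII sigma s - z_CaMKII CaMKII`; with
#'   `camkii_coincidence_gated = FALSE` glutamate alone drives it
#'   (`b_CaMKII s`).
#' * tPA release requires coincident pre/postsynaptic activity:
#'   `d tPA = p_tPA sigma s - z_tPA tPA`.
#' * proBDNF is released with presynaptic activity (`p_BDNF s`), decays
#'   slowly, and is converted to mBDNF by tPA
#'   (`proBDNF + tPA <-> mBDNF`, forward `k8 proBDNF tPA`, reverse
#'   `k9 mBDNF`).
#' * TrkB/p75 are expressed under MR/GR control
#'   ([receptor_expression_rates()]) and decay linearly.
#' * Activated complexes form by mass action
#'   (`p_actTrkB mBDNF TrkB`, `p_actp75 proBDNF p75`) and decay fast.
#' * `a` relaxes towards the TrkB-minus-p75 signalling balance:
#'   `d a = b_a (actTrkB - actp75) - z_a a` (flip with
#'   `a_sign_convention = "printed"`).
#'
#' @param state Named numeric vector with components `CaMKII`, `tPA`,
#'   `proBDNF`, `mBDNF`, `TrkB`, `p75`, `actTrkB`, `actp75`, `a`.
#' @param s_t Instantaneous presynaptic signal (>= 0).
#' @param sigma Coincidence gain (large for correlated pre/postsynaptic
#'   activity, small or zero for noncorrelated activity).
#' @param C Cortisol concentration (>= 0).
#' @param params A [synplast_params()] set.
#' @return Named numeric vector of derivatives, same layout as `state`.
#' @export
cascade_rhs <- function(state, s_t, sigma, C, params) {
  occ <- receptor_occupancy(C, params)
  expr <- receptor_expression_rates(occ$MR, occ$GR, params)

  conv <- params$k8 * state[["proBDNF"]] * state[["tPA"]] -
    params$k9 * state[["mBDNF"]]
  bind_trkb <- params$p_actTrkB * state[["mBDNF"]] * state[["TrkB"]]
  bind_p75  <- params$p_actp75 * state[["proBDNF"]] * state[["p75"]]
  consume <- if (isTRUE(params$consume_on_binding)) 1 else 0
  a_sign <- if (identical(params$a_sign_convention, "printed")) -1 else 1
  camkii_drive <- if (isTRUE(params$camkii_coincidence_gated)) {
    params$b_CaMKII * sigma * s_t
  } else {
    params$b_CaMKII * s_t
  }

  c(
    CaMKII  = camkii_drive - params$z_CaMKII * state[["CaMKII"]],
    tPA     = params$p_tPA * sigma * s_t - params$z_tPA * state[["tPA"]],
    proBDNF = params$p_BDNF * s_t - params$z_proBDNF * state[["proBDNF"]] -
      conv - consume * bind_p75,
    mBDNF   = conv - consume * bind_trkb,
    TrkB    = expr$trkb_production - params$z_TrkB * state[["TrkB"]] -
      consume * bind_trkb,
    p75     = expr$p75_production - params$z_p75 * state[["p75"]] -
      consume * bind_p75,
    actTrkB = bind_trkb - params$z_actTrkB * state[["actTrkB"]],
    actp75  = bind_p75 - params$z_actp75 * state[["actp75"]],
    a       = a_sign * params$b_a *
      (state[["actTrkB"]] - state[["actp75"]]) - params$z_a * state[["a"]]
  )
}
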