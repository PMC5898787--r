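#' Membrane trafficking of heteromeric AMPA receptor dimers
#'
#' The cytosolic heteromer pool `R_S R_L` is inserted into the membrane by
#' a CaMKII-catalysed reaction (rate `k11`), removed by a
#' glutamate-catalysed decomposition (rate `k12_removal`; glutamate release
#' is identified with the presynaptic signal `s(t)`), and leaves the
#' membrane spontaneously (rate `k12_vanish`):
#' \deqn{\frac{d[R_SR_L^{mem}]}{dt} = k_{11}[R_SR_L][CaMKII]
#'   - k_{12}^{rm}[R_SR_L^{mem}]\,s(t) - k_{12}^{van}[R_SR_L^{mem}].}
#' The two removal processes share the printed rate symbol; they are kept
#' as separate parameters (both defaulting to 1) so that knockout and
#' sensitivity studies can distinguish them.
#'
#' @param RSRL_mem Membrane heteromer concentration (>= 0).
#' @param heteromer Cytosolic heteromer pool, from [dimer_pools()].
#' @param CaMKII Activated CaMKII concentration (>= 0).
#' @param s_t Instantaneous presynaptic signal (glutamate) level.
#' @param params A [synplast_params()] set.
#' @return The scalar time derivative of `RSRL_mem`.
#' @export
membrane_rhs <- function(RSRL_mem, heteromer, CaMKII, s_t, params) {
  params$k11 * heteromer * CaMKII -
    params$k12_removal * RSRL_mem * s_t -
    params$k12_vanish * RSRL_mem
}

#' Membrane pool of activated homomers
#'
#' The membrane homomer pool is proportional to the cytosolic homomer pool
#' (itself at quasi-steady state with \eqn{[R'_S]}):
#' \deqn{[R'_SR'_S^{mem}] = \phi\,(k_1/k_2)\,[R'_S]^2}
#' with proportionality constant `homomer_membrane_fraction`.
#'
#' @param RpS Activated subunit concentration (vectorised, >= 0).
#' @param params A [synplast_params()] set.
#' @return Membrane homomer concentration.
#' @export
homomer_membrane <- function(RpS, params) {
  params$homomer_membrane_fraction * (params$k1 / params$k2) * RpS^2
}

#' Transmitted signal
#'
#' The postsynaptic response to a presynaptic signal is carried by the
#' membrane-resident AMPA receptor pools:
#' \deqn{s_{in}(t) = 2\,([R'_SR'_S^{mem}] + [R_SR_L^{mem}])\,s(t).}
#' It is linear (homogeneous of degree one) both in the pooled membrane
#' concentration and in the signal, so transmission fold changes are
#' independent of the probe amplitude.
#'
#' @param homomer_mem,RSRL_mem Membrane pool concentrations (>= 0,
#'   vectorised).
#' @param s_t Presynaptic signal level.
#' @return The transmitted signal.
#' @examples
#' transmitted_signal(0.25, 0.1, 1)
#' @export
transmitted_signal <- function(homomer_mem, RSRL_mem, s_t) {
  if (any(homomer_mem < 0) || any(RSRL_mem < 0)) {
    stop("transmitted_signal(): membrane pools must be nonnegative",
         call. = FALSE)
  }
  2 * (homomer_mem + RSRL_mem) * s_t
}
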