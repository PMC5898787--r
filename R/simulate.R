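#' State vector layout of the full model
#'
#' @return Character vector of the 13 dynamical species, in integration
#'   order: core (`NSF`, `RS`, `RpS`), cascade (`CaMKII`, `tPA`,
#'   `proBDNF`, `mBDNF`, `TrkB`, `p75`, `actTrkB`, `actp75`, `a`), and
#'   membrane (`RSRL_mem`).
#' @export
state_names <- function() {
  c("NSF", "RS", "RpS",
    "CaMKII", "tPA", "proBDNF", "mBDNF", "TrkB", "p75",
    "actTrkB", "actp75", "a",
    "RSRL_mem")
}

# Apply protocol knockouts (parameter names forced to zero).
.apply_knockouts <- function(params, knockouts) {
  for (nm in knockouts) {
    if (!nm %in% names(params)) {
      stop("unknown knockout parameter: ", nm, call. = FALSE)
    }
    params[[nm]] <- 0
  }
  params
}

# Full coupled right-hand side as a closure over (params, protocol).
.make_full_rhs <- function(params, prot, curves = param_curves(params)) {
  cascade_idx <- 4:12
  force(params); force(prot); force(curves)
  function(t, y) {
    s_t <- waveform_value(prot$signal, t)
    C_t <- waveform_value(prot$cortisol, t)
    mult <- waveform_value(prot$pnsf_schedule, t)

    a <- y[[12L]]
    eff <- effective_production(a, params$p_NSF * mult, params$p_RS, params)
    core <- core_rhs(c(NSF = y[[1L]], RS = y[[2L]], RpS = y[[3L]]),
                     eff$p_NSF_eff, eff$p_RS_eff, params, curves)
    casc <- cascade_rhs(
      c(CaMKII = y[[4L]], tPA = y[[5L]], proBDNF = y[[6L]],
        mBDNF = y[[7L]], TrkB = y[[8L]], p75 = y[[9L]],
        actTrkB = y[[10L]], actp75 = y[[11L]], a = a),
      s_t, prot$sigma, C_t, params)
    het <- (params$k5 / params$k6) * y[[2L]] * params$R_L
    memb <- membrane_rhs(y[[13L]], het, y[[4L]], s_t, params)
    if (isTRUE(params$recycle_heteromers)) {
      core[["RS"]] <- core[["RS"]] +
        params$k12_removal * y[[13L]] * s_t
    }
    c(core, casc, memb)
  }
}

#' Pre-equilibrated initial state
#'
#' Initial condition for scenario simulations: the core system sits at one
#' of its stable stationary points (the middle "active" state by default),
#' the receptor expression levels `TrkB`/`p75` are at their
#' cortisol-conditioned steady states, and every activity-driven species
#' (CaMKII, tPA, BDNF pools, activated complexes, `a`, membrane
#' heteromers) is zero -- the exact fixed point that 10 h of silent
#' pre-equilibration converges to.
#'
#' @param params A [synplast_params()] set.
#' @param cortisol Cortisol level conditioning the receptor expression.
#' @param start_at Which stable core point to start from: `"active"`,
#'   `"LTD"` or `"LTP"`.
#' @return Named numeric state vector (see [state_names()]).
#' @export
initial_state <- function(params, cortisol = 0, start_at = "active") {
  start_at <- match.arg(start_at, c("active", "LTD", "LTP"))
  eq <- find_stationary_points(params)
  pick <- eq[eq$label == start_at & eq$stability == "stable", ]
  if (nrow(pick) != 1) {
    stop("initial_state(): no unique '", start_at,
         "' stationary point for these parameters", call. = FALSE)
  }
  occ <- receptor_occupancy(cortisol, params)
  expr <- receptor_expression_rates(occ$MR, occ$GR, params)
  y <- stats::setNames(numeric(13), state_names())
  y["NSF"] <- pick$NSF; y["RS"] <- pick$RS; y["RpS"] <- pick$RpS
  y["TrkB"] <- expr$trkb_production / params$z_TrkB
  y["p75"] <- expr$p75_production / params$z_p75
  y
}

#' Integrate the full coupled model under a protocol
#'
#' Solves the 13-species system (core activation + cascade + membrane)
#' with an embedded Dormand--Prince 5(4) pair, restarting at every
#' waveform discontinuity, and records the state on a regular output grid
#' together with the derived membrane homomer pool and the transmitted
#' signal \eqn{s_{in}(t)}.
#'
#' @param params A [synplast_params()] set.
#' @param prot A [protocol()].
#' @param y0 Initial state; defaults to [initial_state()] conditioned on
#'   the cortisol level at `t = 0`.
#' @param rtol,atol Relative / absolute integration tolerances.
#' @param dt_record Output grid spacing in hours.
#' @param extra_record_times Additional times (e.g. probe times) forced
#'   onto the output grid.
#' @return A tibble of class `synplast_trajectory`: columns `time`, the 13
#'   state variables, `homomer_mem`, `s`, and `s_in`; attributes carry the
#'   parameters, protocol and integrator statistics.
#' @examples
#' \donttest{
#' p <- synplast_params()
#' tr <- simulate_protocol(p, protocol(horizon = 2, signal = 0, sigma = 0,
#'                                     cortisol = 0.1))
#' tail(tr)
#' }
#' @export
simulate_protocol <- function(params, prot, y0 = NULL,
                              rtol = 1e-8, atol = 1e-10, dt_record = 0.01,
                              extra_record_times = numeric(0)) {
  stopifnot(inherits(prot, "synplast_protocol"))
  params <- .apply_knockouts(params, prot$knockouts)
  validate_params(params)
  if (is.null(y0)) {
    y0 <- initial_state(params,
                        cortisol = waveform_value(prot$cortisol, 0))
  }
  stopifnot(length(y0) == 13L)
  names(y0) <- state_names()
  rec <- sort(unique(c(seq(0, prot$horizon, by = dt_record),
                       prot$horizon, extra_record_times)))
  f <- .make_full_rhs(params, prot)
  sol <- .ode_dp45(f, y0, 0, prot$horizon, record_times = rec,
                   breaks = .protocol_breaks(prot),
                   rtol = rtol, atol = atol)
  states <- tibble::as_tibble(as.data.frame(sol$states))
  out <- dplyr::bind_cols(tibble::tibble(time = sol$times), states)
  out$homomer_mem <- homomer_membrane(out$RpS, params)
  out$s <- waveform_value(prot$signal, out$time)
  out$s_in <- transmitted_signal(out$homomer_mem,
                                 pmax(out$RSRL_mem, 0), out$s)
  class(out) <- c("synplast_trajectory", class(out))
  attr(out, "params") <- params
  attr(out, "protocol") <- prot
  attr(out, "solver") <- list(n_steps = sol$n_steps,
                              n_rejected = sol$n_rejected,
                              rtol = rtol, atol = atol)
  out
}

# Interpolate trajectory columns at an arbitrary time (linear).
.trajectory_at <- function(traj, t, cols) {
  if (t < min(traj$time) - 1e-9 || t > max(traj$time) + 1e-9) {
    stop("time ", format(t), " outside the recorded trajectory",
         call. = FALSE)
  }
  vapply(cols, function(cl) {
    stats::approx(traj$time, traj[[cl]], xout = t, rule = 2)$y
  }, numeric(1))
}
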