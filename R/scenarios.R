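#' Scenario constants
#'
#' Protocol constants shared by the named experiments, fixed once by
#' calibrating the model's free inputs against the qualitative outcomes
#' of the simulated experiments (see the vignette for the calibration
#' rationale).  The two stimulation families mirror the electrophysiology
#' they stand for: correlated activity is a short, sharp tetanus (the
#' high-frequency-stimulation analogue: amplitude 0.12 on `[0.5, 1]` h
#' with a large coincidence gain `sigma = 29`), noncorrelated activity is
#' a longer, stronger low-frequency drive with no coincidence
#' (`sigma = 0`: glutamate is released but the postsynaptic cell is not
#' coincidentally depolarised, so no tPA reaches the cleft).  Cortisol
#' levels are "low (normal)" (`C = 0.5`: MR saturated, GR occupancy 9%),
#' "high" (`C = 20`: GR occupancy 80%) and "zero" (`C = 0`, the
#' receptor-blockade condition).  Transmission is probed with a standard
#' test pulse before the stimulation and at the 5 h outcome point.
#' Intervention experiments scale the NSF production by 3 during the
#' first hour and reduce it (strong: x0.3, small: x0.8) from `t = 4` over
#' a configurable window.
#'
#' @return Named list of protocol constants.
#' @export
scenario_constants <- function() {
  list(
    stim_start = 0.5,
    stim_end_correlated = 1.0, stim_end_noncorrelated = 2.0,
    stim_amplitude_correlated = 0.12, stim_amplitude_noncorrelated = 0.25,
    sigma_correlated = 29, sigma_noncorrelated = 0,
    cortisol_low = 0.5, cortisol_high = 20, cortisol_zero = 0,
    horizon = 5, probe_baseline = 0.25, probe_final = 5,
    fig8_elevation = 3, fig8_elevation_end = 1,
    fig8_reduction_strong = 0.3, fig8_reduction_small = 0.8,
    fig8_reduction_start = 4, fig8_window = 1,
    fig8_horizon = 12, settle_time = 6
  )
}

#' Registered simulation scenarios
#'
#' One row per named experiment: the six cortisol-by-coincidence
#' stimulation scenarios (`fig4a`/`fig4b`/`fig4c` correlated at low, high
#' and zero cortisol; `fig5a`/`fig5b`/`fig5c` noncorrelated likewise),
#' the same six with the membrane-insertion knockout `k11 = 0`
#' (`fig6_low/high/zero`, `fig7_low/high/zero`), and the two NSF
#' intervention protocols (`fig8_left` strong reduction, `fig8_right`
#' small reduction).
#'
#' @param k Scenario constants, defaulting to [scenario_constants()].
#' @return A tibble with columns `name`, `family` (`"correlated"`,
#'   `"noncorrelated"` or `"intervention"`), `cortisol`, `k11_knockout`,
#'   `intervention`, `description`.
#' @export
scenario_registry <- function(k = scenario_constants()) {
  tibble::tribble(
    ~name, ~family, ~cortisol, ~k11_knockout, ~intervention, ~description,
    "fig4a", "correlated", k$cortisol_low, FALSE, NA_character_,
    "correlated activity, low (normal) cortisol: full LTP",
    "fig4b", "correlated", k$cortisol_high, FALSE, NA_character_,
    "correlated activity, high cortisol: attenuated LTP",
    "fig4c", "correlated", k$cortisol_zero, FALSE, NA_character_,
    "correlated activity, no cortisol: marginal change",
    "fig5a", "noncorrelated", k$cortisol_low, FALSE, NA_character_,
    "noncorrelated activity, low cortisol: small LTD",
    "fig5b", "noncorrelated", k$cortisol_high, FALSE, NA_character_,
    "noncorrelated activity, high cortisol: marked LTD",
    "fig5c", "noncorrelated", k$cortisol_zero, FALSE, NA_character_,
    "noncorrelated activity, no cortisol: small change only",
    "fig6_low", "correlated", k$cortisol_low, TRUE, NA_character_,
    "fig4a with membrane heteromer insertion prevented (k11 = 0)",
    "fig6_high", "correlated", k$cortisol_high, TRUE, NA_character_,
    "fig4b with k11 = 0",
    "fig6_zero", "correlated", k$cortisol_zero, TRUE, NA_character_,
    "fig4c with k11 = 0",
    "fig7_low", "noncorrelated", k$cortisol_low, TRUE, NA_character_,
    "fig5a with k11 = 0",
    "fig7_high", "noncorrelated", k$cortisol_high, TRUE, NA_character_,
    "fig5b with k11 = 0",
    "fig7_zero", "noncorrelated", k$cortisol_zero, TRUE, NA_character_,
    "fig5c with k11 = 0",
    "fig8_left", "intervention", k$cortisol_low, FALSE, "strong",
    "NSF elevation then strong reduction: LTP converts to LTD",
    "fig8_right", "intervention", k$cortisol_low, FALSE, "small",
    "NSF elevation then small reduction: LTP tends to persist"
  )
}

# Build the protocol for a registry row (with constant overrides).
.scenario_protocol <- function(row, k = scenario_constants(),
                               fig8_window = k$fig8_window) {
  knock <- if (row$k11_knockout) "k11" else character()
  if (is.na(row$intervention)) {
    corr <- row$family == "correlated"
    protocol(
      horizon = k$horizon,
      signal = boxcar(
        k$stim_start,
        if (corr) k$stim_end_correlated else k$stim_end_noncorrelated,
        if (corr) k$stim_amplitude_correlated else k$stim_amplitude_noncorrelated
      ),
      sigma = if (corr) k$sigma_correlated else k$sigma_noncorrelated,
      cortisol = row$cortisol,
      knockouts = knock
    )
  } else {
    mag <- if (row$intervention == "strong") {
      k$fig8_reduction_strong
    } else {
      k$fig8_reduction_small
    }
    protocol(
      horizon = k$fig8_horizon,
      signal = 0, sigma = 0, cortisol = row$cortisol,
      pnsf_schedule = .pnsf_intervention(k$fig8_elevation,
                                         k$fig8_elevation_end,
                                         k$fig8_reduction_start,
                                         fig8_window, mag),
      knockouts = knock
    )
  }
}

# Elevation x`elev` on [0, t_elev], baseline, then x`mag` on
# [t_red, t_red + window].
.pnsf_intervention <- function(elev, t_elev, t_red, window, mag) {
  if (window <= 0) {
    pw_const(t_elev, c(elev, 1))
  } else {
    pw_const(c(t_elev, t_red, t_red + window), c(elev, 1, mag, 1))
  }
}

#' Probe the transmission fold change of a trajectory
#'
#' Transmission is measured with a standard test pulse: the transmitted
#' signal [transmitted_signal()] that a probe of amplitude
#' `probe_amplitude` would evoke given the membrane pools at the probe
#' time.  The fold change `final / baseline` is independent of the probe
#' amplitude (the readout is linear in the signal).
#'
#' @param traj A `synplast_trajectory` from [simulate_protocol()].
#' @param probe_times Length-2 numeric: baseline and outcome probe times;
#'   the baseline probe must precede the stimulation window.
#' @param probe_amplitude Probe pulse height (> 0).
#' @return A list with components `baseline`, `final`, `fold_change`.
#' @export
probe_transmission <- function(traj, probe_times = c(0.25, 5),
                               probe_amplitude = 1) {
  stopifnot(length(probe_times) == 2, probe_amplitude > 0)
  pools <- vapply(probe_times, function(t) {
    v <- .trajectory_at(traj, t, c("homomer_mem", "RSRL_mem"))
    v[["homomer_mem"]] + max(v[["RSRL_mem"]], 0)
  }, numeric(1))
  baseline <- transmitted_signal(pools[1], 0, probe_amplitude)
  final <- transmitted_signal(pools[2], 0, probe_amplitude)
  if (baseline <= 0) {
    stop("probe_transmission(): zero baseline transmission ",
         "(uninitialised synapse)", call. = FALSE)
  }
  list(baseline = baseline, final = final, fold_change = final / baseline)
}

#' Classify the end state of a simulation by basin of attraction
#'
#' Determines which stable stationary point of the core system a simulated
#' synapse has committed to.  The full model is continued in silence
#' (`s = 0`, cortisol held at the scenario level) until the cascade has
#' decayed and the protein production rates have returned to baseline --
#' the slow proBDNF decay makes this restoration gradual, which is exactly
#' what lets a depressed synapse find the nearby depressed equilibrium
#' instead of overshooting back to the active state -- and the label of
#' the stable stationary point the core settles on is reported.  This is
#' basin membership under the model's own relaxation dynamics, not a
#' threshold on transmission.
#'
#' @param full_state Named numeric state vector of length 13 (see
#'   [state_names()]); a length-3 core state `(NSF, RS, RpS)` is also
#'   accepted and padded with a quiescent cascade.
#' @param params A [synplast_params()] set.
#' @param cortisol Cortisol level held during the silent continuation.
#' @param t_settle Silent continuation horizon (hours); long enough for
#'   the slowest cascade species (proBDNF, decay 0.1/h) to vanish.
#' @return One of `"LTD"`, `"active"`, `"LTP"` (or `"unlabeled"` when the
#'   baseline system is not tristable).
#' @export
classify_state <- function(full_state, params, cortisol = 0,
                           t_settle = 250) {
  if (length(full_state) == 3L) {
    y <- stats::setNames(numeric(13), state_names())
    y[c("NSF", "RS", "RpS")] <-
      full_state[c("NSF", "RS", "RpS")]
    full_state <- y
  }
  stopifnot(length(full_state) == 13L)
  names(full_state) <- state_names()
  prot <- protocol(horizon = t_settle, signal = 0, sigma = 0,
                   cortisol = cortisol)
  f <- .make_full_rhs(params, prot)
  sol <- .ode_dp45(f, full_state, 0, t_settle, record_times = t_settle,
                   rtol = 1e-8, atol = 1e-10)
  y <- sol$states[nrow(sol$states), ]
  # polish the core to its stationary point
  curves <- param_curves(params)
  fc <- function(t, z) {
    core_rhs(c(NSF = z[[1L]], RS = z[[2L]], RpS = z[[3L]]),
             params$p_NSF, params$p_RS, params, curves)
  }
  z <- y[c("NSF", "RS", "RpS")]
  for (i in 1:8) {
    if (max(abs(fc(0, z))) < 1e-9) break
    sol2 <- .ode_dp45(fc, z, 0, 50, record_times = 50,
                      rtol = 1e-9, atol = 1e-11)
    z <- sol2$states[nrow(sol2$states), ]
  }
  eq <- find_stationary_points(params)
  stable <- eq[eq$stability == "stable", ]
  stable$label[which.min(abs(stable$RpS - z[["RpS"]]))]
}

#' Run a named scenario
#'
#' Looks up `name` in the [scenario_registry()], builds its protocol,
#' pre-equilibrates the synapse at the scenario's cortisol level with the
#' core in the middle "active" state, integrates the full model, probes
#' the transmission fold change, and classifies the end state by basin
#' membership.
#'
#' @param name A registered scenario name; see [scenario_registry()].
#' @param params A [synplast_params()] set.
#' @param overrides Named list patching [scenario_constants()] (e.g.
#'   `list(cortisol_low = 0.5)`).
#' @param rtol,atol Integration tolerances.
#' @return An object of class `synplast_scenario`: a list with elements
#'   `name`, `trajectory`, `baseline_transmission`, `final_transmission`,
#'   `fold_change`, `classification`, `protocol`, `params`.
#' @examples
#' \donttest{
#' res <- run_scenario("fig4a")
#' res$fold_change
#' res$classification
#' }
#' @export
run_scenario <- function(name, params = synplast_params(),
                         overrides = list(), rtol = 1e-8, atol = 1e-10) {
  k <- scenario_constants()
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(k))
    if (length(unknown)) {
      stop("unknown scenario constant(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    k[names(overrides)] <- overrides
  }
  reg <- scenario_registry(k)
  if (!name %in% reg$name) {
    stop("unknown scenario '", name, "'; registered scenarios: ",
         paste(reg$name, collapse = ", "), call. = FALSE)
  }
  row <- reg[reg$name == name, ]
  prot <- .scenario_protocol(row, k)
  probe_final <- if (is.na(row$intervention)) k$probe_final else prot$horizon
  probe_base <- if (is.na(row$intervention)) k$probe_baseline else 0
  sim_params <- .apply_knockouts(params, prot$knockouts)
  y0 <- initial_state(sim_params, cortisol = row$cortisol,
                      start_at = "active")
  traj <- simulate_protocol(params, prot, y0 = y0, rtol = rtol, atol = atol,
                            extra_record_times = c(probe_base, probe_final))
  pr <- probe_transmission(traj, c(probe_base, probe_final))
  terminal <- .trajectory_at(traj, prot$horizon, state_names())
  cls <- classify_state(terminal, sim_params, cortisol = row$cortisol)
  structure(
    list(name = name, trajectory = traj,
         baseline_transmission = pr$baseline,
         final_transmission = pr$final,
         fold_change = pr$fold_change,
         classification = cls,
         protocol = prot, params = sim_params),
    class = "synplast_scenario"
  )
}

#' @export
print.synplast_scenario <- function(x, ...) {
  cat(sprintf(
    "<scenario %s> fold change %.3f (baseline %.4g -> final %.4g), end state: %s\n",
    x$name, x$fold_change, x$baseline_transmission, x$final_transmission,
    x$classification))
  invisible(x)
}

#' Scan NSF-reduction window lengths for LTP-to-LTD conversion
#'
#' Prepares the synapse in LTP with an initial NSF-production elevation,
#' then applies a production reduction of factor `decrease_magnitude`
#' starting at `t = 4` for each window length in `window_lengths`, lets
#' the system settle, and classifies the end state.  A strong reduction
#' converts LTP to LTD for all but an underproportionally short range of
#' window lengths; a small reduction leaves an overproportionally long
#' range that ends in the middle active state or LTP instead.
#'
#' @param decrease_magnitude Multiplier on the baseline NSF production
#'   during the reduction window (in `[0, 1)`).
#' @param window_lengths Numeric vector of window lengths (hours, >= 0).
#' @param params A [synplast_params()] set.
#' @param overrides Named list patching [scenario_constants()].
#' @param rtol,atol Integration tolerances.
#' @return A tibble with columns `window_length` and `classification`.
#' @export
intervention_window_scan <- function(decrease_magnitude,
                                     window_lengths = seq(0, 3, by = 0.25),
                                     params = synplast_params(),
                                     overrides = list(),
                                     rtol = 1e-8, atol = 1e-10) {
  stopifnot(decrease_magnitude >= 0, decrease_magnitude < 1,
            all(window_lengths >= 0))
  k <- scenario_constants()
  k[names(overrides)] <- overrides
  y0 <- initial_state(params, cortisol = k$cortisol_low,
                      start_at = "active")
  cls <- vapply(window_lengths, function(w) {
    horizon <- k$fig8_reduction_start + w + k$settle_time
    prot <- protocol(
      horizon = horizon, signal = 0, sigma = 0,
      cortisol = k$cortisol_low,
      pnsf_schedule = .pnsf_intervention(k$fig8_elevation,
                                         k$fig8_elevation_end,
                                         k$fig8_reduction_start,
                                         w, decrease_magnitude)
    )
    traj <- simulate_protocol(params, prot, y0 = y0, rtol = rtol,
                              atol = atol, dt_record = 0.05)
    terminal <- .trajectory_at(traj, horizon, state_names())
    classify_state(terminal, params, cortisol = k$cortisol_low)
  }, character(1))
  tibble::tibble(window_length = window_lengths, classification = cls)
}
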