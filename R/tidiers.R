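#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulated trajectory into long format
#'
#' One row per time point and variable (`time`, `variable`, `value`),
#' the layout used by the CSV exports and by [autoplot.synplast_trajectory()].
#'
#' @param x A `synplast_trajectory`.
#' @param ... Unused.
#' @return A long tibble.
#' @method tidy synplast_trajectory
#' @export
tidy.synplast_trajectory <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"time",
                      names_to = "variable", values_to = "value")
}

#' @rdname tidy.synplast_trajectory
#' @method glance synplast_trajectory
#' @export
glance.synplast_trajectory <- function(x, ...) {
  st <- attr(x, "solver")
  tibble::tibble(
    horizon = max(x$time), n_recorded = nrow(x),
    n_steps = st$n_steps, n_rejected = st$n_rejected,
    rtol = st$rtol, atol = st$atol
  )
}

#' Tidy and summarise scenario results
#'
#' `tidy()` returns the one-row outcome table (probes, fold change,
#' classification); `glance()` adds integrator statistics.
#'
#' @param x A `synplast_scenario` from [run_scenario()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy synplast_scenario
#' @export
tidy.synplast_scenario <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    baseline_transmission = x$baseline_transmission,
    final_transmission = x$final_transmission,
    fold_change = x$fold_change,
    classification = x$classification
  )
}

#' @rdname tidy.synplast_scenario
#' @method glance synplast_scenario
#' @export
glance.synplast_scenario <- function(x, ...) {
  dplyr::bind_cols(tidy(x), glance(x$trajectory))
}

#' @method tidy synplast_equilibria
#' @export
tidy.synplast_equilibria <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("RpS", "RS", "NSF", "stability", "label")])
}

#' @method glance synplast_equilibria
#' @export
glance.synplast_equilibria <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x),
    n_stable = sum(x$stability == "stable"),
    p_NSF_eff = attr(x, "p_NSF_eff"),
    p_RS_eff = attr(x, "p_RS_eff")
  )
}

#' Plot a simulated trajectory
#'
#' Facetted time courses in the layout of the simulation figures: cytosolic
#' subunits and NSF; protein production modulation; BDNF pools; signalling
#' complexes; membrane pools and transmitted signal.
#'
#' @param object A `synplast_trajectory`.
#' @param variables Optional character vector restricting the panels.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot synplast_trajectory
#' @export
autoplot.synplast_trajectory <- function(object, variables = NULL, ...) {
  long <- tidy.synplast_trajectory(object)
  groups <- c(
    NSF = "cytosolic pool", RS = "cytosolic pool", RpS = "cytosolic pool",
    CaMKII = "kinase / protease", tPA = "kinase / protease",
    proBDNF = "BDNF", mBDNF = "BDNF",
    TrkB = "receptors", p75 = "receptors",
    actTrkB = "signalling", actp75 = "signalling", a = "signalling",
    RSRL_mem = "membrane / output", homomer_mem = "membrane / output",
    s = "membrane / output", s_in = "membrane / output"
  )
  long <- long[long$variable %in% names(groups), ]
  if (!is.null(variables)) long <- long[long$variable %in% variables, ]
  long$panel <- factor(groups[long$variable], levels = unique(groups))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$time, y = .data$value,
                               colour = .data$variable)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "normalised concentration",
                  colour = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot a bifurcation sweep
#'
#' Stationary \eqn{[R'_S]} branches against the NSF production rate, solid
#' for stable and dashed for unstable points, shaded by regime.
#'
#' @param object A `synplast_bifurcation` from [pnsf_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot synplast_bifurcation
#' @export
autoplot.synplast_bifurcation <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_NSF, y = .data$RpS)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$stability,
                                     colour = .data$regime), size = 0.8) +
    ggplot2::scale_shape_manual(values = c(stable = 16, unstable = 1)) +
    ggplot2::labs(x = "NSF production rate",
                  y = "stationary [R'_S]") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot the scissors decomposition
#'
#' The production blade `P` and the magnitude of the decay blade `|D|` of
#' the reduced stationary equation over the admissible \eqn{[R'_S]}
#' interval; their intersections are the stationary points (the
#' bistable-switch geometry of the model).
#'
#' @param params A [synplast_params()] set.
#' @param p_NSF_eff,p_RS_eff Effective production rates.
#' @param n Number of grid points.
#' @return A ggplot object.
#' @export
plot_scissors <- function(params, p_NSF_eff = params$p_NSF,
                          p_RS_eff = params$p_RS, n = 400) {
  iv <- admissible_interval(params, p_NSF_eff, p_RS_eff)
  grid <- seq(iv[1], iv[2], length.out = n)
  st <- scissors_terms(grid, params, p_NSF_eff, p_RS_eff)
  df <- tibble::tibble(
    RpS = rep(grid, 2),
    value = c(st$P, -st$D),
    blade = rep(c("production P", "decay |D|"), each = n)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$RpS, y = .data$value,
                                   colour = .data$blade)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "[R'_S]", y = "rate", colour = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}
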