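#' Model parameters
#'
#' Builds the full parameter set of the synaptic plasticity model: the core
#' AMPA-subunit activation system, the glucocorticoid/BDNF cascade, and
#' membrane trafficking.  Concentrations are normalised (dimensionless) and
#' time is measured in hours.  All rate parameters default to 1 except the
#' handful with distinguished values: the Michaelis constants of the two
#' corticosteroid receptors (`M_MR = 1e-4`, `M_GR = 5`, expressing the much
#' higher cortisol affinity of MR), the NSF production sensitivity
#' (`u_NSF = 3`), the slow decays of tPA and proBDNF (`z_tPA = 0.5`,
#' `z_proBDNF = 0.1`), the fast decays of the activated receptor complexes
#' (`z_actTrkB = 2`, `z_actp75 = 2`), and the elevated production gains
#' (`p_BDNF = 10`, `p_actTrkB = 10`, `p_tPA = 2`).
#'
#' The S-shaped kinetics \eqn{k_0([R'_S])} and \eqn{k_4([R_S])} default to
#' piecewise-linear curves calibrated once, via [find_stationary_points()],
#' so that the normalised parameter set has exactly five stationary points
#' (three stable separated by two unstable) and the potentiated state
#' carries roughly twice the baseline transmission; see the package
#' vignette for the calibration.
#'
#' @param ... Named parameter overrides, e.g. `synplast_params(k11 = 0)`.
#'   Unknown names are rejected.
#'
#' @return A named list of class `synplast_params`.
#'
#' @section Switches:
#' * `scurve_shape`: `"piecewise_linear"` (default) or `"smooth_sigmoid"`.
#' * `a_sign_convention`: `"text"` (default) makes the production-modulation
#'   variable `a` rise with activated TrkB and fall with activated p75;
#'   `"printed"` flips the sign (see the vignette for why the default is
#'   the biologically consistent reading).
#' * `consume_on_binding`: if `TRUE` (default), formation of activated
#'   ligand-receptor complexes consumes the free ligand and receptor
#'   (conservative mass-action binding, so a bound ligand pool is cleared
#'   by its receptors); `FALSE` treats complex formation as catalytic
#'   sensing.
#' * `camkii_coincidence_gated`: if `TRUE` (default), CaMKII activation is
#'   driven by coincident pre/postsynaptic activity (`b_CaMKII sigma s`),
#'   reflecting its Ca2+/calmodulin dependence downstream of the NMDA
#'   receptor; `FALSE` drives it by glutamate alone (`b_CaMKII s`).
#' * `recycle_heteromers`: if `TRUE`, glutamate-catalysed decomposition of
#'   membrane heteromers returns the short-tailed subunit to the cytosolic
#'   pool.
#'
#' @examples
#' p <- synplast_params()
#' p$M_GR
#' synplast_params(k11 = 0)$k11
#' @export
synplast_params <- function(...) {
  defaults <- list(
    ## --- core: [NSF], [R_S], [R'_S] -------------------------------------
    p_NSF = 1, p_RS = 1,
    z_NSF = 1, z_RS = 1, z_RpS = 1,
    k1 = 1, k2 = 1,            # homomer  2 R'_S <-> R'_S R'_S
    k5 = 1, k6 = 1,            # heteromer R_S + R_L <-> R_S R_L
    R_L = 1,                   # free long-tailed subunit pool (constant)
    ## calibrated S-curves (see vignette)
    k0_low = 2.4, k0_high = 6.37, k0_rise_start = 0.58, k0_rise_end = 0.63,
    k4_low = 0.2, k4_high = 2.9, k4_rise_start = 0.58, k4_rise_end = 0.66,
    scurve_shape = "piecewise_linear",
    ## --- cascade: stimulation and cortisol ------------------------------
    b_CaMKII = 1, z_CaMKII = 1,
    p_tPA = 2, z_tPA = 0.5,
    k8 = 1, k9 = 1,
    p_BDNF = 10, z_proBDNF = 0.1,
    M_MR = 1e-4, M_GR = 5,
    p_TrkB_expr = 1, z_TrkB = 1,
    p_p75_expr = 1, z_p75 = 1,
    p_actTrkB = 10, z_actTrkB = 2,
    p_actp75 = 1, z_actp75 = 2,
    b_a = 1, z_a = 1,
    u_NSF = 3, u_RS = 1,
    ## --- membrane trafficking -------------------------------------------
    k11 = 1,
    k12_removal = 1, k12_vanish = 1,
    homomer_membrane_fraction = 4,
    ## --- switches ---------------------------------------------------------
    a_sign_convention = "text",
    consume_on_binding = TRUE,
    camkii_coincidence_gated = TRUE,
    recycle_heteromers = FALSE,
    seed = 0L                  # reserved; the model is fully deterministic
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over)))) {
      stop("synplast_params(): all overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown)) {
      stop("synplast_params(): unknown parameter(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    defaults[names(over)] <- over
  }
  params <- structure(defaults, class = "synplast_params")
  validate_params(params)
  params
}

#' @rdname synplast_params
#' @export
default_parameters <- function() synplast_params()

#' Validate a parameter set
#'
#' Checks sign constraints (all rates nonnegative, strictly positive
#' dissociation rates `k2`, `k6` so the quasi-steady-state dimer pools are
#' defined), the receptor affinity ordering `M_MR < M_GR`, the S-curve ramp
#' windows, and the switch values.  Called by [synplast_params()]; exposed
#' so that externally assembled configurations can be checked too.
#'
#' @param params A `synplast_params` object (or plain named list with the
#'   same fields).
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_params <- function(params) {
  num <- setdiff(names(params),
                 c("scurve_shape", "a_sign_convention", "consume_on_binding",
                   "camkii_coincidence_gated", "recycle_heteromers", "seed"))
  for (nm in num) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop("validate_params(): '", nm, "' must be a single number",
           call. = FALSE)
    }
    if (!grepl("rise", nm) && v < 0) {
      stop("validate_params(): '", nm, "' must be nonnegative", call. = FALSE)
    }
  }
  if (params$k2 <= 0 || params$k6 <= 0) {
    stop("validate_params(): 'k2' and 'k6' must be strictly positive",
         call. = FALSE)
  }
  if (!(params$M_MR < params$M_GR)) {
    stop("validate_params(): 'M_MR' must be below 'M_GR' ",
         "(MR binds cortisol with the higher affinity)", call. = FALSE)
  }
  if (!(params$k0_rise_start < params$k0_rise_end)) {
    stop("validate_params(): 'k0_rise_start' must be below 'k0_rise_end'",
         call. = FALSE)
  }
  if (!(params$k4_rise_start < params$k4_rise_end)) {
    stop("validate_params(): 'k4_rise_start' must be below 'k4_rise_end'",
         call. = FALSE)
  }
  if (!params$scurve_shape %in% c("piecewise_linear", "smooth_sigmoid")) {
    stop("validate_params(): 'scurve_shape' must be 'piecewise_linear' or ",
         "'smooth_sigmoid'", call. = FALSE)
  }
  if (!params$a_sign_convention %in% c("text", "printed")) {
    stop("validate_params(): 'a_sign_convention' must be 'text' or 'printed'",
         call. = FALSE)
  }
  for (nm in c("consume_on_binding", "camkii_coincidence_gated",
               "recycle_heteromers")) {
    if (!is.logical(params[[nm]]) || length(params[[nm]]) != 1L ||
        is.na(params[[nm]])) {
      stop("validate_params(): '", nm, "' must be TRUE or FALSE",
           call. = FALSE)
    }
  }
  invisible(params)
}

#' Extract the two S-curves from a parameter set
#'
#' @param params A `synplast_params` object.
#' @return A list with elements `k0` (activation rate as a function of
#'   activated subunits) and `k4` (deactivation rate as a function of
#'   nonactivated subunits), both `synplast_scurve`s.
#' @export
param_curves <- function(params) {
  list(
    k0 = s_curve(params$k0_low, params$k0_high,
                 params$k0_rise_start, params$k0_rise_end,
                 params$scurve_shape),
    k4 = s_curve(params$k4_low, params$k4_high,
                 params$k4_rise_start, params$k4_rise_end,
                 params$scurve_shape)
  )
}

#' @export
print.synplast_params <- function(x, ...) {
  cat("<synplast_params> normalised units, time in hours\n")
  nondefault <- list()
  ref <- unclass(synplast_params())
  for (nm in names(x)) {
    if (!identical(x[[nm]], ref[[nm]])) nondefault[[nm]] <- x[[nm]]
  }
  if (length(nondefault)) {
    cat("  overrides:",
        paste(names(nondefault), vapply(nondefault, format, ""),
              sep = " = ", collapse = ", "), "\n")
  } else {
    cat("  all parameters at defaults\n")
  }
  invisible(x)
}
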