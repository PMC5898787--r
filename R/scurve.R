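#' S-shaped rate laws for the nonlinear activation kinetics
#'
#' The activation rate \eqn{k_0} and the deactivation rate \eqn{k_4} of
#' short-tailed AMPA receptor subunits are not mass-action constants: they
#' are saturating, S-shaped functions of the homomer- and heteromer-forming
#' species.  `s_curve()` builds such a rate law from two plateau values and
#' the concentration window over which the curve ramps from one plateau to
#' the other.
#'
#' Two functional forms are supported.  `"piecewise_linear"` interpolates
#' linearly between the plateaus (the kinked form makes the intersection
#' geometry of the stationary-point analysis easy to read), while
#' `"smooth_sigmoid"` is a logistic ramp matched to the same plateaus; the
#' two agree exactly on the plateaus and the qualitative multi-stability of
#' the system does not depend on the choice.
#'
#' @param low_rate Plateau value attained for small arguments (>= 0).
#' @param high_rate Plateau value attained for large arguments (>= 0).
#' @param rise_start Concentration at which the ramp begins.
#' @param rise_end Concentration at which the ramp ends
#'   (`rise_start < rise_end`).
#' @param shape Either `"piecewise_linear"` or `"smooth_sigmoid"`.
#'
#' @return An object of class `synplast_scurve`.
#'
#' @details A curve built by `s_curve()` is monotone nondecreasing when
#' `low_rate <= high_rate`.  Use [mirror_s_curve()] to obtain the monotone
#' nonincreasing mirror image (plateaus swapped) of an existing curve.
#'
#' @examples
#' k0 <- s_curve(1, 8, rise_start = 0.4, rise_end = 0.6)
#' scurve_value(k0, c(0, 0.5, 2))
#' @export
s_curve <- function(low_rate, high_rate, rise_start, rise_end,
                    shape = c("piecewise_linear", "smooth_sigmoid")) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(low_rate), length(low_rate) == 1L,
            is.numeric(high_rate), length(high_rate) == 1L,
            is.numeric(rise_start), length(rise_start) == 1L,
            is.numeric(rise_end), length(rise_end) == 1L)
  if (low_rate < 0 || high_rate < 0) {
    stop("s_curve(): plateau rates must be nonnegative", call. = FALSE)
  }
  if (!(rise_start < rise_end)) {
    stop("s_curve(): 'rise_start' must be strictly below 'rise_end'",
         call. = FALSE)
  }
  structure(
    list(low_rate = low_rate, high_rate = high_rate,
         rise_start = rise_start, rise_end = rise_end, shape = shape),
    class = "synplast_scurve"
  )
}

#' Mirror an S-curve
#'
#' Swaps the two plateaus of an S-curve, turning a monotone nondecreasing
#' rate law into a nonincreasing one over the same ramp window (and vice
#' versa).  Useful to express a rate that falls, rather than rises, with its
#' controlling concentration.
#'
#' @param curve A `synplast_scurve`.
#' @return A `synplast_scurve` with `low_rate` and `high_rate` exchanged.
#' @export
mirror_s_curve <- function(curve) {
  stopifnot(inherits(curve, "synplast_scurve"))
  s_curve(curve$high_rate, curve$low_rate, curve$rise_start, curve$rise_end,
          curve$shape)
}

# Logistic steepness such that at the ramp edges the sigmoid has covered
# 99% of the plateau-to-plateau span; beyond the edges the curve is within
# 1% of the plateau, and numerically identical a short distance further out.
.scurve_logistic_k <- function(curve) {
  2 * log(99) / (curve$rise_end - curve$rise_start)
}

#' Evaluate an S-curve
#'
#' @param curve A `synplast_scurve`.
#' @param x Nonnegative concentrations (vectorised).
#' @return Rate values, bounded by the two plateaus.
#' @export
scurve_value <- function(curve, x) {
  stopifnot(inherits(curve, "synplast_scurve"), is.numeric(x))
  if (any(x < 0)) {
    stop("scurve_value(): negative concentration argument", call. = FALSE)
  }
  lo <- curve$low_rate
  hi <- curve$high_rate
  if (curve$shape == "piecewise_linear") {
    f <- (x - curve$rise_start) / (curve$rise_end - curve$rise_start)
    f <- pmin(pmax(f, 0), 1)
    lo + (hi - lo) * f
  } else {
    k <- .scurve_logistic_k(curve)
    mid <- (curve$rise_start + curve$rise_end) / 2
    lo + (hi - lo) / (1 + exp(-k * (x - mid)))
  }
}

#' Slope of an S-curve
#'
#' One-sided derivative of the rate law; for the piecewise-linear form the
#' ramp slope is returned inside the open ramp window and 0 on the plateaus
#' (kink points included with the plateau).
#'
#' @inheritParams scurve_value
#' @return Derivative values.
#' @keywords internal
scurve_slope <- function(curve, x) {
  stopifnot(inherits(curve, "synplast_scurve"), is.numeric(x))
  lo <- curve$low_rate
  hi <- curve$high_rate
  if (curve$shape == "piecewise_linear") {
    s <- (hi - lo) / (curve$rise_end - curve$rise_start)
    ifelse(x > curve$rise_start & x < curve$rise_end, s, 0)
  } else {
    k <- .scurve_logistic_k(curve)
    mid <- (curve$rise_start + curve$rise_end) / 2
    e <- exp(-k * (x - mid))
    (hi - lo) * k * e / (1 + e)^2
  }
}

#' @export
print.synplast_scurve <- function(x, ...) {
  dir <- if (x$high_rate >= x$low_rate) "nondecreasing" else "nonincreasing"
  cat(sprintf("<S-curve (%s, %s)> plateaus %.4g -> %.4g, ramp [%.4g, %.4g]\n",
              x$shape, dir, x$low_rate, x$high_rate,
              x$rise_start, x$rise_end))
  invisible(x)
}
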