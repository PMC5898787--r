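#' Admissible interval for the reduced stationary problem
#'
#' At a stationary point of the core system the interaction term cancels
#' between the three equations, giving the complementary relation
#' \deqn{p_{NSF} - z_{NSF}[NSF] = p_{R_S} - z_{R_S}[R_S] = z_{R'_S}[R'_S],}
#' so both \eqn{[R_S]} and \eqn{[NSF]} are affine functions of
#' \eqn{[R'_S]}.  They stay nonnegative only for
#' \eqn{[R'_S] \in [0, \min(p_{R_S}, p_{NSF})/z_{R'_S}]}; that interval is
#' the domain of the scalar reduced equation.
#'
#' @param params A [synplast_params()] set.
#' @param p_NSF_eff,p_RS_eff Effective production rates (default: the
#'   baseline productions in `params`).
#' @return `c(lower, upper)`; errors if the interval is empty.
#' @export
admissible_interval <- function(params, p_NSF_eff = params$p_NSF,
                                p_RS_eff = params$p_RS) {
  hi <- min(p_RS_eff, p_NSF_eff) / params$z_RpS
  if (!is.finite(hi) || hi < 0) {
    stop("admissible_interval(): inconsistent parameters ",
         "(empty admissible interval)", call. = FALSE)
  }
  c(0, hi)
}

# [R_S] and [NSF] implied by the complementary relation at a given [R'_S].
.complementary_state <- function(RpS, params, p_NSF_eff, p_RS_eff) {
  list(
    RS  = (p_RS_eff - params$z_RpS * RpS) / params$z_RS,
    NSF = (p_NSF_eff - params$z_RpS * RpS) / params$z_NSF
  )
}

#' Scissors decomposition of the reduced stationary equation
#'
#' Substituting the complementary relation into the \eqn{[R'_S]} equation
#' splits the stationary condition into a nonnegative production blade
#' \deqn{P = k_0([R'_S])\,[R_S]([R'_S])\,[NSF]([R'_S])}
#' and a nonpositive decay blade
#' \deqn{D = -(z_{R'_S} + k_4([R_S]))\,[R'_S];}
#' stationary points are the intersections \eqn{P + D = 0}.  Raising the
#' NSF production rate lifts the production blade (via
#' \eqn{[NSF]([R'_S])}), which is how transient production changes open and
#' close the LTD/LTP regimes.
#'
#' @param RpS Activated subunit concentrations inside the
#'   [admissible_interval()] (vectorised).
#' @inheritParams admissible_interval
#' @return A list with components `P` (>= 0) and `D` (<= 0).
#' @export
scissors_terms <- function(RpS, params, p_NSF_eff = params$p_NSF,
                           p_RS_eff = params$p_RS) {
  iv <- admissible_interval(params, p_NSF_eff, p_RS_eff)
  if (any(RpS < iv[1] - 1e-12) || any(RpS > iv[2] + 1e-12)) {
    stop("scissors_terms(): [R'_S] outside the admissible interval ",
         sprintf("[%.6g, %.6g]", iv[1], iv[2]),
         " (an implied concentration would be negative)", call. = FALSE)
  }
  curves <- param_curves(params)
  cs <- .complementary_state(RpS, params, p_NSF_eff, p_RS_eff)
  RS <- pmax(cs$RS, 0); NSF <- pmax(cs$NSF, 0)
  list(
    P = scurve_value(curves$k0, RpS) * RS * NSF,
    D = -(params$z_RpS + scurve_value(curves$k4, RS)) * RpS
  )
}

#' Residual of the reduced stationary equation
#'
#' `P + D` from [scissors_terms()]; its zeros on the admissible interval
#' are exactly the stationary points of the full three-dimensional core
#' system.
#'
#' @inheritParams scissors_terms
#' @return Numeric residual values (vectorised).
#' @export
stationary_residual <- function(RpS, params, p_NSF_eff = params$p_NSF,
                                p_RS_eff = params$p_RS) {
  st <- scissors_terms(RpS, params, p_NSF_eff, p_RS_eff)
  st$P + st$D
}

#' Linear stability of a core stationary point
#'
#' Classifies a stationary point by the eigenvalues of the analytic 3x3
#' Jacobian of [core_rhs()]: stable iff every eigenvalue has negative real
#' part.  As a cross-check the one-dimensional criterion -- the sign of the
#' derivative of [stationary_residual()] -- must agree; both are computed
#' and a disagreement or a (near-)marginal eigenvalue raises an error
#' rather than silently mislabelling a degenerate point.
#'
#' @param RpS Stationary value of \eqn{[R'_S]}.
#' @inheritParams admissible_interval
#' @param tol Marginality tolerance on the dominant real part.
#' @return `"stable"` or `"unstable"`.
#' @export
classify_stability <- function(RpS, params, p_NSF_eff = params$p_NSF,
                               p_RS_eff = params$p_RS, tol = 1e-7) {
  cs <- .complementary_state(RpS, params, p_NSF_eff, p_RS_eff)
  state <- c(NSF = cs$NSF, RS = cs$RS, RpS = RpS)
  ev <- eigen(core_jacobian(state, params), only.values = TRUE)$values
  top <- max(Re(ev))
  if (abs(top) < tol) {
    stop("classify_stability(): marginal stationary point ",
         sprintf("(dominant eigenvalue real part %.3g at [R'_S] = %.6g)",
                 top, RpS), call. = FALSE)
  }
  eig_stable <- top < 0
  h <- max(1e-7, 1e-7 * abs(RpS))
  iv <- admissible_interval(params, p_NSF_eff, p_RS_eff)
  lo <- max(iv[1], RpS - h); hi <- min(iv[2], RpS + h)
  slope <- (stationary_residual(hi, params, p_NSF_eff, p_RS_eff) -
              stationary_residual(lo, params, p_NSF_eff, p_RS_eff)) /
    (hi - lo)
  if (abs(slope) > 1e-6 && ((slope < 0) != eig_stable)) {
    stop("classify_stability(): 1-D slope criterion and 3-D eigenvalue ",
         "criterion disagree at [R'_S] = ", format(RpS), call. = FALSE)
  }
  if (eig_stable) "stable" else "unstable"
}

#' Stationary points of the core activation system
#'
#' Finds all stationary points by bracketing sign changes of the reduced
#' residual on a uniform grid over the admissible interval and refining
#' each bracket with [stats::uniroot()] to machine-level tolerance, then
#' attaches linear stability ([classify_stability()]) and the LTD / active
#' / LTP labels.  With the calibrated default parameters the system is
#' tristable: five stationary points in the pattern
#' stable--unstable--stable--unstable--stable.
#'
#' @inheritParams admissible_interval
#' @param grid_resolution Number of grid cells used for bracketing
#'   (>= 1000).
#' @param label_reference Optional `synplast_equilibria` tibble computed at
#'   the baseline productions, used to label stationary points of perturbed
#'   systems by proximity; by default labels are assigned directly when the
#'   system is tristable (ascending \eqn{[R'_S]}: LTD, active, LTP) and by
#'   nearest baseline stable point otherwise.
#' @return A tibble of class `synplast_equilibria` with columns `RpS`,
#'   `RS`, `NSF`, `stability`, `label`, ordered by ascending `RpS`.
#' @examples
#' find_stationary_points(synplast_params())
#' @export
find_stationary_points <- function(params, p_NSF_eff = params$p_NSF,
                                   p_RS_eff = params$p_RS,
                                   grid_resolution = 2000,
                                   label_reference = NULL) {
  stopifnot(grid_resolution >= 1000)
  iv <- admissible_interval(params, p_NSF_eff, p_RS_eff)
  grid <- seq(iv[1], iv[2], length.out = grid_resolution + 1)
  res <- stationary_residual(grid, params, p_NSF_eff, p_RS_eff)

  roots <- numeric(0)
  for (i in seq_len(grid_resolution)) {
    r1 <- res[i]; r2 <- res[i + 1]
    if (r1 == 0 && (i == 1 || res[i - 1] != 0)) {
      roots <- c(roots, grid[i])
    } else if (r1 * r2 < 0) {
      root <- stats::uniroot(
        function(x) stationary_residual(x, params, p_NSF_eff, p_RS_eff),
        lower = grid[i], upper = grid[i + 1], tol = 1e-12
      )$root
      roots <- c(roots, root)
    }
  }
  if (res[grid_resolution + 1] == 0) roots <- c(roots, iv[2])
  roots <- sort(unique(roots))
  # merge refinement duplicates straddling a grid node
  if (length(roots) > 1) {
    roots <- roots[c(TRUE, diff(roots) > 1e-9 * max(1, iv[2]))]
  }

  cs <- .complementary_state(roots, params, p_NSF_eff, p_RS_eff)
  stability <- vapply(
    roots, classify_stability, character(1),
    params = params, p_NSF_eff = p_NSF_eff, p_RS_eff = p_RS_eff
  )
  out <- tibble::tibble(
    RpS = roots, RS = cs$RS, NSF = cs$NSF,
    stability = stability,
    label = "unlabeled"
  )

  is_stable <- out$stability == "stable"
  if (sum(is_stable) == 3) {
    out$label[is_stable] <- c("LTD", "active", "LTP")
  } else if (!is.null(label_reference)) {
    ref <- label_reference[label_reference$stability == "stable", ]
    if (nrow(ref) == 3) {
      out$label[is_stable] <- vapply(
        out$RpS[is_stable],
        function(r) ref$label[which.min(abs(ref$RpS - r))],
        character(1)
      )
    }
  }
  class(out) <- c("synplast_equilibria", class(out))
  attr(out, "p_NSF_eff") <- p_NSF_eff
  attr(out, "p_RS_eff") <- p_RS_eff
  out
}

#' Bifurcation sweep over the NSF production rate
#'
#' Recomputes the stationary-point set along a grid of NSF production
#' rates and classifies each grid point into one of three regimes:
#' `monostable_LTD` (only the depressed state exists), `tristable`
#' (LTD / active / LTP coexist), `monostable_LTP`.  Along an increasing
#' sweep through the calibrated default system the regime sequence is
#' monostable_LTD, tristable, monostable_LTP with exactly two fold
#' transitions -- the hysteresis loop that makes transient production
#' changes act as a plasticity switch.
#'
#' @param params A [synplast_params()] set.
#' @param p_NSF_range Length-2 numeric range of NSF production rates.
#' @param n_steps Number of grid points (>= 2).
#' @param grid_resolution Passed on to [find_stationary_points()].
#' @return A tibble of class `synplast_bifurcation`: one row per stationary
#'   point per grid value, columns `p_NSF`, `RpS`, `RS`, `NSF`,
#'   `stability`, `label`, `regime`.
#' @examples
#' \donttest{
#' sweep <- pnsf_sweep(synplast_params(), c(0.4, 2.0), n_steps = 60)
#' dplyr::count(sweep, regime)
#' }
#' @export
pnsf_sweep <- function(params, p_NSF_range, n_steps = 100,
                       grid_resolution = 1500) {
  stopifnot(length(p_NSF_range) == 2, n_steps >= 2)
  ref <- find_stationary_points(params, grid_resolution = grid_resolution)
  grid <- seq(p_NSF_range[1], p_NSF_range[2], length.out = n_steps)
  rows <- purrr::map(grid, function(p) {
    pts <- find_stationary_points(params, p_NSF_eff = p,
                                  grid_resolution = grid_resolution,
                                  label_reference = ref)
    n_stable <- sum(pts$stability == "stable")
    regime <- if (n_stable >= 3) {
      "tristable"
    } else if (n_stable == 2) {
      "bistable"
    } else if (any(pts$label == "LTP" & pts$stability == "stable")) {
      "monostable_LTP"
    } else if (any(pts$label == "LTD" & pts$stability == "stable")) {
      "monostable_LTD"
    } else {
      "monostable_other"
    }
    dplyr::mutate(tibble::as_tibble(pts), p_NSF = p, regime = regime,
                  .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("synplast_bifurcation", class(out))
  out
}

#' Export a bifurcation table as CSV
#'
#' Writes the sweep in a flat RFC-4180 layout (header row, `.` decimal
#' separator, UTF-8) with columns `p_NSF`, `RpS`, `RS`, `NSF`,
#' `stability`, `label`, `regime`.
#'
#' @param sweep A `synplast_bifurcation` tibble from [pnsf_sweep()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bifurcation_csv <- function(sweep, path) {
  cols <- c("p_NSF", "RpS", "RS", "NSF", "stability", "label", "regime")
  utils::write.csv(as.data.frame(sweep)[, cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.synplast_equilibria <- function(x, ...) {
  cat(sprintf(
    "<stationary points> %d found (%d stable) at p_NSF_eff = %.4g\n",
    nrow(x), sum(x$stability == "stable"), attr(x, "p_NSF_eff")))
  NextMethod()
}
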