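#' Piecewise-constant waveforms
#'
#' Stimulation protocols are built from right-open piecewise-constant
#' waveforms: `pw_const(breaks, values)` takes `n` strictly increasing
#' break times and `n + 1` values (the level before the first break, the
#' level on each inter-break interval, and the level after the last
#' break).  `boxcar()` is the common special case of a single rectangular
#' pulse.
#'
#' @param breaks Strictly increasing numeric vector of switch times (may
#'   be empty for a constant waveform).
#' @param values Numeric vector of length `length(breaks) + 1`; all values
#'   must be nonnegative for signal and cortisol waveforms.
#' @return An object of class `synplast_waveform`.
#' @examples
#' s <- boxcar(0.5, 1.0, amplitude = 1)
#' waveform_value(s, c(0.25, 0.75, 2))
#' @export
pw_const <- function(breaks, values) {
  breaks <- as.numeric(breaks)
  values <- as.numeric(values)
  if (length(breaks) && any(diff(breaks) <= 0)) {
    stop("pw_const(): 'breaks' must be strictly increasing", call. = FALSE)
  }
  if (length(values) != length(breaks) + 1L) {
    stop("pw_const(): need length(values) == length(breaks) + 1",
         call. = FALSE)
  }
  structure(list(breaks = breaks, values = values),
            class = "synplast_waveform")
}

#' @rdname pw_const
#' @param t0,t1 Pulse onset and offset times (`t0 < t1`).
#' @param amplitude Pulse height.
#' @export
boxcar <- function(t0, t1, amplitude = 1) {
  pw_const(c(t0, t1), c(0, amplitude, 0))
}

#' @rdname pw_const
#' @param w A `synplast_waveform` or a single number (treated as a
#'   constant waveform).
#' @param t Times at which to evaluate (vectorised).
#' @export
waveform_value <- function(w, t) {
  if (is.numeric(w) && length(w) == 1L) return(rep(w, length(t)))
  stopifnot(inherits(w, "synplast_waveform"))
  w$values[findInterval(t, w$breaks) + 1L]
}

.as_waveform <- function(w) {
  if (inherits(w, "synplast_waveform")) return(w)
  if (is.numeric(w) && length(w) == 1L) return(pw_const(numeric(0), w))
  stop("expected a 'synplast_waveform' or a single number", call. = FALSE)
}

#' Stimulation protocol
#'
#' Bundles the time-dependent inputs of a simulation: the presynaptic
#' signal waveform `s(t)`, the pre/post coincidence gain `sigma`, the
#' cortisol waveform `C(t)`, an optional multiplicative schedule on the
#' baseline NSF production rate (used by the intervention experiments),
#' and a set of parameter knockouts (parameter names forced to zero, e.g.
#' `"k11"` to prevent heteromer insertion into the membrane).
#'
#' @param horizon Simulation horizon in hours (> 0).
#' @param signal Presynaptic signal: a [pw_const()]/[boxcar()] waveform or
#'   a single nonnegative number.
#' @param sigma Coincidence gain (>= 0).
#' @param cortisol Cortisol level: waveform or single nonnegative number.
#' @param pnsf_schedule Multiplier on the baseline NSF production:
#'   waveform or single number (default 1; values >= 0).
#' @param knockouts Character vector of parameter names to force to zero.
#' @return An object of class `synplast_protocol`.
#' @examples
#' protocol(horizon = 5, signal = boxcar(0.5, 1), sigma = 1, cortisol = 0.1)
#' @export
protocol <- function(horizon, signal = 0, sigma = 1, cortisol = 0,
                     pnsf_schedule = 1, knockouts = character()) {
  stopifnot(is.numeric(horizon), length(horizon) == 1L, horizon > 0,
            is.numeric(sigma), length(sigma) == 1L, sigma >= 0,
            is.character(knockouts))
  signal <- .as_waveform(signal)
  cortisol <- .as_waveform(cortisol)
  pnsf_schedule <- .as_waveform(pnsf_schedule)
  for (nm in c("signal", "cortisol", "pnsf_schedule")) {
    w <- get(nm)
    if (any(w$values < 0)) {
      stop("protocol(): '", nm, "' waveform must be nonnegative",
           call. = FALSE)
    }
  }
  structure(
    list(horizon = horizon, signal = signal, sigma = sigma,
         cortisol = cortisol, pnsf_schedule = pnsf_schedule,
         knockouts = knockouts),
    class = "synplast_protocol"
  )
}

# All waveform discontinuities inside (0, horizon); the integrator is
# restarted at each of these so no step straddles a jump.
.protocol_breaks <- function(prot) {
  b <- c(prot$signal$breaks, prot$cortisol$breaks, prot$pnsf_schedule$breaks)
  sort(unique(b[b > 0 & b < prot$horizon]))
}

#' @export
print.synplast_protocol <- function(x, ...) {
  cat(sprintf(
    "<protocol> horizon %.3g h, sigma = %.3g, %d signal break(s), %d knockout(s)\n",
    x$horizon, x$sigma, length(x$signal$breaks), length(x$knockouts)))
  invisible(x)
}
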