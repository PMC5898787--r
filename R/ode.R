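# Adaptive explicit Runge-Kutta integration (Dormand-Prince 5(4)).
#
# The model is a small (13-dimensional), moderately stiff-free reaction
# system with piecewise-constant inputs; an embedded RK pair with PI step
# control, restarted at every input discontinuity, resolves it to the
# requested tolerances without a compiled solver.  The integrator lands
# exactly on every requested output time (steps are clipped, never
# interpolated), so recorded states carry full solver accuracy.

.dp_c <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
.dp_a <- list(
  numeric(0),
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
)
.dp_b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
.dp_b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
            187 / 2100, 1 / 40)

# f(t, y) -> dy; y0 named numeric; record_times must include t0 and t1 and
# every discontinuity in `breaks` relevant to f.  Returns list(times,
# states [matrix, rows = times], n_steps, n_rejected).
.ode_dp45 <- function(f, y0, t0, t1, record_times, breaks = numeric(0),
                      rtol = 1e-8, atol = 1e-10, h_max = Inf,
                      max_steps = 5e6) {
  stopifnot(t1 > t0)
  mandatory <- sort(unique(c(t0, t1, breaks,
                             record_times[record_times > t0 &
                                            record_times < t1])))
  record_set <- sort(unique(c(t0, t1,
                              record_times[record_times >= t0 &
                                             record_times <= t1])))
  n <- length(y0)
  out_t <- numeric(length(record_set))
  out_y <- matrix(NA_real_, nrow = length(record_set), ncol = n,
                  dimnames = list(NULL, names(y0)))
  rec_i <- 1L
  record <- function(t, y) {
    out_t[rec_i] <<- t
    out_y[rec_i, ] <<- y
    rec_i <<- rec_i + 1L
  }

  t <- t0
  y <- y0
  record(t, y)
  next_rec <- 2L
  h <- min((t1 - t0) / 100, h_max, 0.1)
  n_steps <- 0L
  n_rej <- 0L
  k <- matrix(0, nrow = n, ncol = 7)
  f_cur <- f(t, y)                     # FSAL

  safety <- 0.9; min_scale <- 0.2; max_scale <- 5; alpha <- 0.2
  err_prev <- 1

  while (t < t1 - 1e-14 * max(1, abs(t1))) {
    if (n_steps >= max_steps) {
      stop("integration failed: step budget exhausted at t = ",
           format(t), call. = FALSE)
    }
    # never step across a mandatory time (discontinuity or record point)
    upcoming <- mandatory[mandatory > t + 1e-14 * max(1, abs(t))]
    t_stop <- if (length(upcoming)) upcoming[1] else t1
    h <- min(h, t_stop - t, h_max)
    if (h <= 0 || !is.finite(h)) {
      stop("integration failed: nonpositive step at t = ", format(t),
           call. = FALSE)
    }

    k[, 1] <- f_cur
    for (s in 2:7) {
      ys <- y + h * as.vector(k[, seq_len(s - 1), drop = FALSE] %*%
                                .dp_a[[s]])
      k[, s] <- f(t + .dp_c[s] * h, ys)
    }
    y5 <- y + h * as.vector(k %*% .dp_b5)
    y4 <- y + h * as.vector(k %*% .dp_b4)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (!is.finite(err)) {
      stop("integration failed: nonfinite state at t = ", format(t),
           call. = FALSE)
    }

    if (err <= 1) {
      t_new <- t + h
      hit_stop <- abs(t_new - t_stop) <= 1e-12 * max(1, abs(t_stop))
      if (hit_stop) t_new <- t_stop
      t <- t_new
      y <- y5
      f_cur <- if (hit_stop) f(t, y) else k[, 7]  # FSAL only within a piece
      n_steps <- n_steps + 1L
      if (next_rec <= length(record_set) &&
          abs(t - record_set[next_rec]) <= 1e-12 * max(1, abs(t))) {
        record(t, y)
        next_rec <- next_rec + 1L
      }
      # PI controller
      scale <- safety * err^(-0.7 * alpha) * err_prev^(0.4 * alpha)
      if (err == 0) scale <- max_scale
      h <- h * min(max_scale, max(min_scale, scale))
      err_prev <- max(err, 1e-4)
    } else {
      n_rej <- n_rej + 1L
      h <- h * max(min_scale, safety * err^(-alpha))
    }
  }
  if (rec_i <= length(record_set)) {
    # numerical shortfall on the final point; record terminal state
    record(t, y)
  }
  list(times = out_t[seq_len(rec_i - 1L)],
       states = out_y[seq_len(rec_i - 1L), , drop = FALSE],
       n_steps = n_steps, n_rejected = n_rej)
}
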