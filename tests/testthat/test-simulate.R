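test_that("the adaptive integrator reproduces a known linear system", {
  # dy = A y with diagonalisable A: closed-form matrix exponential
  f <- function(t, y) c(-0.5 * y[1] + 0.2 * y[2], -1.5 * y[2])
  y0 <- c(a = 1, b = 2)
  sol <- synplast:::.ode_dp45(f, y0, 0, 4, record_times = 4,
                              rtol = 1e-10, atol = 1e-12)
  y_end <- sol$states[nrow(sol$states), ]
  b_exact <- 2 * exp(-1.5 * 4)
  a_exact <- (1 + 0.4) * exp(-0.5 * 4) - 0.4 * exp(-1.5 * 4)
  expect_equal(unname(y_end[2]), b_exact, tolerance = 1e-9)
  expect_equal(unname(y_end[1]), a_exact, tolerance = 1e-9)
})

test_that("a silent protocol holds the pre-equilibrated synapse still", {
  p <- synplast_params()
  prot <- protocol(horizon = 5, signal = 0, sigma = 0, cortisol = 0.5)
  tr <- simulate_protocol(p, prot)
  y0 <- initial_state(p, cortisol = 0.5)
  for (v in c("NSF", "RS", "RpS", "TrkB", "p75")) {
    expect_lt(max(abs(tr[[v]] - y0[[v]])), 1e-4)
  }
  expect_lt(max(abs(tr$a)), 1e-8)
})

test_that("trajectories stay nonnegative to solver tolerance", {
  p <- synplast_params()
  prot <- protocol(horizon = 5, signal = boxcar(0.5, 1.0, 0.12), sigma = 29,
                   cortisol = 0.5)
  tr <- simulate_protocol(p, prot)
  state_cols <- as.matrix(tr[, setdiff(state_names(), "a")])
  expect_gt(min(state_cols), -1e-10)
})

test_that("recorded states are invariant under output-grid refinement", {
  p <- synplast_params()
  prot <- protocol(horizon = 2, signal = boxcar(0.5, 1.0, 0.12), sigma = 29,
                   cortisol = 0.5)
  tr1 <- simulate_protocol(p, prot, dt_record = 0.05)
  tr2 <- simulate_protocol(p, prot, dt_record = 0.01)
  shared <- intersect(round(tr1$time, 10), round(tr2$time, 10))
  m1 <- as.matrix(tr1[round(tr1$time, 10) %in% shared, state_names()])
  m2 <- as.matrix(tr2[round(tr2$time, 10) %in% shared, state_names()])
  expect_equal(m1, m2, tolerance = 1e-7)
})

test_that("halving the tolerances leaves the fold change unchanged", {
  res1 <- run_scenario("fig4c", rtol = 1e-8, atol = 1e-10)
  res2 <- run_scenario("fig4c", rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(res1$fold_change - res2$fold_change), 1e-4)
})

test_that("integration failures carry the failing time", {
  f <- function(t, y) c(y[1]^2)      # finite-time blow-up at t = 1
  expect_error(
    synplast:::.ode_dp45(f, c(x = 1), 0, 2, record_times = 2,
                         rtol = 1e-8, atol = 1e-10, max_steps = 2000),
    "t = ")
})
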