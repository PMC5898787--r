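test_that("quasi-steady-state dimer pools follow mass action", {
  p <- synplast_params()
  expect_equal(dimer_pools(RS = 1, RpS = 0, p)$homomer, 0)
  p1 <- synplast_params(k1 = 1, k2 = 1, k5 = 1, k6 = 1, R_L = 1)
  expect_equal(dimer_pools(RS = 2, RpS = 0.3, p1)$heteromer, 2)
  expect_equal(dimer_pools(RS = 1, RpS = 0.8, p1)$homomer,
               4 * dimer_pools(RS = 1, RpS = 0.4, p1)$homomer)
  expect_error(dimer_pools(RS = -1, RpS = 0, p), "nonnegative")
})

test_that("k4 is monotone nondecreasing in the nonactivated subunits", {
  p <- synplast_params()
  curves <- param_curves(p)
  grid <- seq(0, 1.5, length.out = 800)
  expect_true(all(diff(k4_rate(grid, curves$k4)) >= -1e-12))
  expect_true(all(diff(k0_rate(grid, curves$k0)) >= -1e-12))
})

test_that("the interaction term cancels in the conservation identities", {
  p <- synplast_params()
  curves <- param_curves(p)
  for (st in random_core_states(25)) {
    pn <- runif(1, 0, 3); pr <- runif(1, 0, 3)
    d <- core_rhs(st, pn, pr, p, curves)
    expect_equal(d[["NSF"]] - d[["RS"]],
                 (pn - p$z_NSF * st[["NSF"]]) - (pr - p$z_RS * st[["RS"]]),
                 tolerance = 1e-13)
    expect_equal(d[["RS"]] + d[["RpS"]],
                 pr - p$z_RS * st[["RS"]] - p$z_RpS * st[["RpS"]],
                 tolerance = 1e-13)
  }
})

test_that("core_rhs vanishes at the stationary points found independently", {
  p <- synplast_params()
  eq <- find_stationary_points(p)
  for (i in seq_len(nrow(eq))) {
    st <- c(NSF = eq$NSF[i], RS = eq$RS[i], RpS = eq$RpS[i])
    expect_lt(max(abs(core_rhs(st, p$p_NSF, p$p_RS, p))), 1e-8)
  }
})

test_that("analytic core Jacobian matches finite differences", {
  p <- synplast_params()
  st <- c(NSF = 0.7, RS = 0.45, RpS = 0.61)  # inside both S-curve ramps
  J <- synplast:::core_jacobian(st, p)
  h <- 1e-7
  for (j in 1:3) {
    stp <- st; stm <- st
    stp[j] <- stp[j] + h; stm[j] <- stm[j] - h
    fd <- (core_rhs(stp, 1, 1, p) - core_rhs(stm, 1, 1, p)) / (2 * h)
    expect_equal(unname(J[, j]), unname(fd), tolerance = 1e-5)
  }
})
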