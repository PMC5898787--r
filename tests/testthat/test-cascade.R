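test_that("receptor occupancies follow Michaelis-Menten saturation", {
  p <- synplast_params()
  occ0 <- receptor_occupancy(0, p)
  expect_equal(occ0$MR, 0)
  expect_equal(occ0$GR, 0)
  # half-saturation at the Michaelis constants (M_GR = 5, M_MR = 1e-4)
  expect_equal(receptor_occupancy(5, p)$GR, 0.5)
  expect_equal(receptor_occupancy(1e-4, p)$MR, 0.5)
  expect_error(receptor_occupancy(-1, p), "nonnegative")
})

test_that("occupancies are monotone, bounded, and MR-dominated", {
  p <- synplast_params()
  set.seed(11)
  C <- sort(c(0, 10^runif(60, -5, 3)))
  occ <- receptor_occupancy(C, p)
  expect_true(all(diff(occ$MR) >= 0) && all(diff(occ$GR) >= 0))
  expect_true(all(occ$MR < 1) && all(occ$GR < 1))
  expect_true(all(occ$MR >= occ$GR))
})

test_that("receptor expression realises the MR/GR control logic", {
  p <- synplast_params()
  e0 <- receptor_expression_rates(0, 0, p)
  expect_equal(e0$trkb_production, 0)
  expect_equal(e0$p75_production, 0)
  expect_equal(receptor_expression_rates(1, 0, p)$trkb_production,
               p$p_TrkB_expr)
  # bell shape: steady-state TrkB maximal at an interior cortisol level
  C <- 10^seq(-5, 2, length.out = 120)
  occ <- receptor_occupancy(C, p)
  trkb <- receptor_expression_rates(occ$MR, occ$GR, p)$trkb_production /
    p$z_TrkB
  i <- which.max(trkb)
  expect_gt(i, 1)
  expect_lt(i, length(C))
  expect_gt(trkb[i], trkb[1])
  expect_gt(trkb[i], trkb[length(C)])
})

test_that("production modulation is linear with clipping at zero", {
  p <- synplast_params()
  e <- effective_production(0, 1, 1, p)
  expect_equal(e$p_NSF_eff, 1)
  expect_equal(e$p_RS_eff, 1)
  expect_equal(effective_production(-1, 1, 1, p)$p_NSF_eff, 0)  # clipped
  # NSF channel is u_NSF = 3 times more sensitive than a unit channel
  d <- effective_production(0.1, 1, 1, p)
  expect_equal(d$p_NSF_eff - 1, 3 * (d$p_RS_eff - 1))
})

test_that("quiescence is a fixed point and linear subsystems match closed forms", {
  p <- synplast_params()
  z <- stats::setNames(numeric(9),
                       c("CaMKII", "tPA", "proBDNF", "mBDNF", "TrkB", "p75",
                         "actTrkB", "actp75", "a"))
  expect_equal(max(abs(cascade_rhs(z, 0, 1, 0, p))), 0)

  # constant drive: tPA relaxes to p_tPA * sigma * s / z_tPA
  f <- function(t, y) cascade_rhs(y, s_t = 0.4, sigma = 0.7, C = 0, p)
  y_end <- rk4_oracle(f, z, t1 = 45, n_steps = 4500)
  expect_equal(y_end[["tPA"]], p$p_tPA * 0.7 * 0.4 / p$z_tPA,
               tolerance = 1e-6)
  # with no coincidence and no cortisol, conversion never starts:
  # proBDNF accumulates to its own closed form and mBDNF stays at zero
  g <- function(t, y) cascade_rhs(y, s_t = 0.4, sigma = 0, C = 0, p)
  y2 <- rk4_oracle(g, z, t1 = 120, n_steps = 6000)
  expect_equal(y2[["proBDNF"]], p$p_BDNF * 0.4 / p$z_proBDNF,
               tolerance = 1e-4)
  expect_equal(y2[["mBDNF"]], 0)
})

test_that("steady mBDNF increases with the coincidence gain", {
  p <- synplast_params()
  z <- stats::setNames(numeric(9),
                       c("CaMKII", "tPA", "proBDNF", "mBDNF", "TrkB", "p75",
                         "actTrkB", "actp75", "a"))
  m_at <- vapply(c(0, 0.3, 1, 3), function(sg) {
    f <- function(t, y) cascade_rhs(y, s_t = 0.3, sigma = sg, C = 0.5, p)
    rk4_oracle(f, z, t1 = 40, n_steps = 4000)[["mBDNF"]]
  }, numeric(1))
  expect_true(all(diff(m_at) > -1e-10))
})

test_that("the cascade decays to rest without stimulation", {
  p <- synplast_params()
  y0 <- stats::setNames(runif(9, 0.1, 1),
                        c("CaMKII", "tPA", "proBDNF", "mBDNF", "TrkB", "p75",
                          "actTrkB", "actp75", "a"))
  f <- function(t, y) cascade_rhs(y, s_t = 0, sigma = 1, C = 0, p)
  y_end <- rk4_oracle(f, y0, t1 = 250, n_steps = 5000)
  expect_lt(max(abs(y_end)), 1e-6)
})
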