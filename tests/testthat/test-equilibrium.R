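test_that("scissors terms have the stated sign structure", {
  p <- synplast_params()
  st0 <- scissors_terms(0, p)
  expect_equal(st0$D, 0)
  expect_equal(st0$P,
               scurve_value(param_curves(p)$k0, 0) *
                 (p$p_RS / p$z_RS) * (p$p_NSF / p$z_NSF))
  grid <- seq(0, admissible_interval(p)[2], length.out = 50)
  st <- scissors_terms(grid, p)
  expect_true(all(st$D <= 0))
  expect_true(all(st$P >= 0))
  # production blade strictly increasing in the NSF production rate
  for (r in c(0.1, 0.4, 0.6)) {
    Ps <- vapply(c(0.8, 1, 1.3, 1.8), function(pn) {
      scissors_terms(r, p, p_NSF_eff = pn)$P
    }, numeric(1))
    expect_true(all(diff(Ps) > 0))
  }
  expect_error(scissors_terms(1.5, p), "admissible")
})

test_that("root finder agrees with a brute-force sign-change scan", {
  p <- synplast_params()
  for (pn in c(0.6, 1.0, 1.45)) {
    iv <- admissible_interval(p, p_NSF_eff = pn)
    dense <- seq(iv[1], iv[2], length.out = 20000)
    res <- stationary_residual(dense, p, p_NSF_eff = pn)
    n_sign_changes <- sum(res[-1] * res[-length(res)] < 0)
    pts <- find_stationary_points(p, p_NSF_eff = pn)
    expect_equal(nrow(pts), n_sign_changes)
    expect_gt(res[1], 0)   # residual at zero is pure production
    expect_true(all(abs(
      stationary_residual(pts$RpS, p, p_NSF_eff = pn)) < 1e-9))
  }
})

test_that("default parameters give the five-point tristable pattern", {
  p <- synplast_params()
  eq <- find_stationary_points(p)
  expect_equal(nrow(eq), 5)
  expect_equal(eq$stability,
               c("stable", "unstable", "stable", "unstable", "stable"))
  expect_equal(eq$label[eq$stability == "stable"],
               c("LTD", "active", "LTP"))
  expect_true(all(diff(eq$RpS) > 0))
  # complementary relation holds at every point
  expect_true(all(abs(eq$RS - (p$p_RS - p$z_RpS * eq$RpS) / p$z_RS) < 1e-9))
  expect_true(all(abs(eq$NSF - (p$p_NSF - p$z_RpS * eq$RpS) / p$z_NSF) < 1e-9))
})

test_that("1-D slope and 3-D eigenvalue stability criteria agree", {
  p <- synplast_params()
  eq <- find_stationary_points(p)
  h <- 1e-6
  for (i in seq_len(nrow(eq))) {
    slope <- (stationary_residual(eq$RpS[i] + h, p) -
                stationary_residual(eq$RpS[i] - h, p)) / (2 * h)
    expect_equal(eq$stability[i] == "stable", slope < 0)
  }
})

test_that("extreme NSF production leaves a single stable point", {
  p <- synplast_params()
  lo <- find_stationary_points(p, p_NSF_eff = 0.4)
  lo_stable <- lo[lo$stability == "stable", ]
  expect_equal(nrow(lo_stable), 1)
  expect_equal(lo_stable$RpS, min(lo$RpS))   # depressed branch
  hi <- find_stationary_points(p, p_NSF_eff = 2.0)
  hi_stable <- hi[hi$stability == "stable", ]
  expect_equal(nrow(hi_stable), 1)
  expect_equal(hi_stable$RpS, max(hi$RpS))   # potentiated branch
})

test_that("the linear-kinetics limit has a unique stable point", {
  # degenerate (constant) S-curves: equal plateaus
  p <- synplast_params(k0_low = 1.2, k0_high = 1.2,
                       k4_low = 0.7, k4_high = 0.7)
  eq <- find_stationary_points(p)
  expect_equal(nrow(eq), 1)
  expect_equal(eq$stability, "stable")
  # closed-form check via the complementary relation:
  # -(z + k4) R + k0 (1 - R)^2 = 0 with all other rates 1
  r <- eq$RpS
  expect_equal(-(1 + 0.7) * r + 1.2 * (1 - r)^2, 0, tolerance = 1e-9)
})

test_that("sweep structure and CSV export are consistent", {
  p <- synplast_params()
  sw <- pnsf_sweep(p, c(0.9, 1.3), n_steps = 9, grid_resolution = 1200)
  counts <- table(sw$p_NSF)
  expect_true(all(counts %in% c(1, 3, 5)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_bifurcation_csv(sw, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(sw))
  expect_equal(back$RpS, sw$RpS, tolerance = 1e-12)
})
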