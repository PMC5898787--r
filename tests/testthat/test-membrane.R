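test_that("membrane heteromer kinetics match their closed forms", {
  p <- synplast_params()
  expect_equal(membrane_rhs(0, heteromer = 0.5, CaMKII = 1, s_t = 1,
                            synplast_params(k11 = 0)), 0)
  # no kinase, no glutamate: pure exponential exit
  expect_equal(membrane_rhs(0.3, 0.5, 0, 0, p), -p$k12_vanish * 0.3)
  # constant inputs: steady state k11 het CaMKII / (k12_removal s + k12_vanish)
  het <- 0.6; cam <- 0.8; s <- 0.5
  target <- p$k11 * het * cam / (p$k12_removal * s + p$k12_vanish)
  m_end <- rk4_oracle(function(t, y) membrane_rhs(y, het, cam, s, p),
                      c(m = 0), t1 = 30, n_steps = 3000)
  expect_equal(unname(m_end), target, tolerance = 1e-8)
})

test_that("the transmitted signal is the printed bilinear readout", {
  expect_equal(transmitted_signal(0, 0, 3), 0)
  expect_equal(transmitted_signal(0.5, 0.2, 0), 0)
  h <- 0.17; s <- 1.3
  expect_equal(transmitted_signal(h, h, s), 4 * h * s)
  # degree-1 homogeneity in signal and pooled concentration
  expect_equal(transmitted_signal(0.2, 0.1, 2 * s),
               2 * transmitted_signal(0.2, 0.1, s))
  expect_equal(transmitted_signal(0.4, 0.2, s),
               2 * transmitted_signal(0.2, 0.1, s))
  expect_error(transmitted_signal(-0.1, 0, 1), "nonnegative")
})

test_that("k11 knockout keeps the membrane heteromer pool empty", {
  p <- synplast_params(k11 = 0)
  prot <- protocol(horizon = 3, signal = boxcar(0.5, 1.5, 0.5), sigma = 1,
                   cortisol = 0.5)
  tr <- simulate_protocol(p, prot)
  expect_lt(max(abs(tr$RSRL_mem)), 1e-12)
})
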