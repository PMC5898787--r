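test_that("plateaus and linear interpolation are exact", {
  for (shape in c("piecewise_linear", "smooth_sigmoid")) {
    cv <- s_curve(1.5, 8, rise_start = 0.4, rise_end = 0.6, shape = shape)
    expect_equal(scurve_value(cv, 0), 1.5, tolerance = 1e-6)
    expect_equal(scurve_value(cv, 100), 8, tolerance = 1e-6)
  }
  pl <- s_curve(1.5, 8, 0.4, 0.6)
  expect_identical(scurve_value(pl, 0), 1.5)       # left plateau, exact
  expect_identical(scurve_value(pl, 5), 8)          # right plateau, exact
  expect_equal(scurve_value(pl, 0.5), mean(c(1.5, 8)))  # ramp midpoint
})

test_that("evaluation is monotone and bounded for random curves", {
  set.seed(7)
  for (i in 1:20) {
    lo <- runif(1, 0, 2); hi <- lo + runif(1, 0, 10)
    rs <- runif(1, 0, 1); re <- rs + runif(1, 0.05, 1)
    shape <- sample(c("piecewise_linear", "smooth_sigmoid"), 1)
    cv <- s_curve(lo, hi, rs, re, shape)
    x <- sort(runif(200, 0, 2 * re))
    v <- scurve_value(cv, x)
    expect_true(all(diff(v) >= -1e-12))
    expect_true(all(v >= lo - 1e-12 & v <= hi + 1e-12))
    m <- mirror_s_curve(cv)
    vm <- scurve_value(m, x)
    expect_true(all(diff(vm) <= 1e-12))
  }
})

test_that("piecewise and sigmoid variants agree on the plateaus", {
  a <- s_curve(0.2, 3, 0.3, 0.5, "piecewise_linear")
  b <- s_curve(0.2, 3, 0.3, 0.5, "smooth_sigmoid")
  far <- c(0, 0.01, 1.2, 5)
  expect_equal(scurve_value(a, far), scurve_value(b, far), tolerance = 5e-3)
})

test_that("domain and construction errors are raised", {
  cv <- s_curve(1, 2, 0, 1)
  expect_error(scurve_value(cv, -0.1), "negative")
  expect_error(s_curve(-1, 2, 0, 1), "nonnegative")
  expect_error(s_curve(1, 2, 1, 1), "rise_start")
})
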