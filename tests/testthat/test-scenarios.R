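test_that("probe fold changes are linear, symmetric and amplitude-free", {
  traj <- tibble::tibble(
    time = c(0, 1, 2, 3, 4, 5),
    homomer_mem = c(0.2, 0.2, 0.25, 0.3, 0.35, 0.4),
    RSRL_mem = 0
  )
  pr <- probe_transmission(traj, c(0, 1))
  expect_equal(pr$fold_change, 1)            # identical pools
  pr2 <- probe_transmission(traj, c(0, 5))
  expect_equal(pr2$fold_change, 2)           # doubled pooled concentration
  pr3 <- probe_transmission(traj, c(0, 5), probe_amplitude = 17)
  expect_equal(pr3$fold_change, pr2$fold_change)  # homogeneity
  empty <- tibble::tibble(time = 0:1, homomer_mem = 0, RSRL_mem = 0)
  expect_error(probe_transmission(empty, c(0, 1)), "baseline")
})

test_that("the registry is complete and rejects unknown names", {
  reg <- scenario_registry()
  expect_gte(nrow(reg), 14)
  expect_false(any(duplicated(reg$name)))
  expect_true(all(c("fig4a", "fig4b", "fig4c", "fig5a", "fig5b", "fig5c",
                    "fig6_low", "fig6_high", "fig6_zero",
                    "fig7_low", "fig7_high", "fig7_zero",
                    "fig8_left", "fig8_right") %in% reg$name))
  expect_error(run_scenario("nope"), "fig4a")
  expect_error(run_scenario("fig4a", overrides = list(bogus = 1)),
               "bogus")
})

test_that("stationary points classify to their own basins", {
  p <- synplast_params()
  eq <- find_stationary_points(p)
  stable <- eq[eq$stability == "stable", ]
  for (i in seq_len(nrow(stable))) {
    st <- c(NSF = stable$NSF[i], RS = stable$RS[i], RpS = stable$RpS[i])
    expect_equal(classify_state(st, p, t_settle = 20), stable$label[i])
  }
})

test_that("scenario results are well-formed and tidy-able", {
  res <- cached_scenario("fig4c")
  expect_s3_class(res$trajectory, "synplast_trajectory")
  expect_equal(res$fold_change,
               res$final_transmission / res$baseline_transmission)
  td <- tidy(res)
  expect_equal(nrow(td), 1)
  expect_named(td, c("name", "baseline_transmission", "final_transmission",
                     "fold_change", "classification"))
  gl <- glance(res)
  expect_true(gl$n_steps > 0)
  long <- tidy(res$trajectory)
  expect_named(long, c("time", "variable", "value"))
  expect_s3_class(autoplot(res$trajectory), "ggplot")
})
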