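# Shared fixtures and independent oracles for the test suite.

# Fixed-step classical RK4: an integrator independent of the package's
# adaptive Dormand-Prince code, used as a numerical oracle on small systems.
rk4_oracle <- function(f, y0, t1, n_steps = 4000) {
  h <- t1 / n_steps
  y <- y0
  t <- 0
  for (i in seq_len(n_steps)) {
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

# Random nonnegative core states under a fixed seed.
random_core_states <- function(n, seed = 421) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    c(NSF = stats::runif(1, 0, 3), RS = stats::runif(1, 0, 3),
      RpS = stats::runif(1, 0, 2))
  })
}

# Scenario results are expensive (~2 s each); compute each once per test
# run and share across test files.
.scenario_cache <- new.env(parent = emptyenv())
cached_scenario <- function(name) {
  if (is.null(.scenario_cache[[name]])) {
    .scenario_cache[[name]] <- run_scenario(name)
  }
  .scenario_cache[[name]]
}
cached_fold <- function(name) cached_scenario(name)$fold_change
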