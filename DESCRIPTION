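Package: synplast
Title: Stress-Dependent Synaptic Plasticity as a Bistable Reaction-Kinetic Switch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulator of NMDA-receptor-dependent long-term
    potentiation (LTP) and depression (LTD) at a glutamatergic synapse.
    Couples a cytosolic AMPA-receptor-subunit activation system with
    S-shaped feedback kinetics (a double positive feedback loop between
    activated and nonactivated short-tailed subunits), a
    glucocorticoid -> MR/GR -> TrkB/p75 -> BDNF signalling cascade that
    modulates ribosomal protein production, and catalytic membrane
    trafficking of receptor dimers.  Provides stationary-point and
    bifurcation analysis of the core system (the "scissors" decomposition
    into production and decay terms), an adaptive Runge-Kutta integrator
    for the full coupled system, named stimulation scenarios covering
    correlated and noncorrelated pre-/postsynaptic activity at several
    cortisol levels, membrane-insertion knockouts, and NSF-production
    intervention protocols, together with tidy accessors and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
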