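# synplast

Deterministic simulation of stress-dependent synaptic plasticity: when does
a glutamatergic synapse undergo NMDA-receptor-dependent long-term
potentiation (LTP), when long-term depression (LTD), and how do
glucocorticoids tip the balance?

The package is aimed at computational neuroscientists and systems
biologists who want a small, fully inspectable reaction-kinetic model of
the late, protein-synthesis-dependent phase of plasticity — each mechanism
an explicit ODE term, every experiment a reproducible protocol object.

## The model in brief

A cytosolic core describes the activation of short-tailed AMPA receptor
subunits by NSF,

    R_S + NSF  <=>[k0, k4]  R'_S

with S-shaped, state-dependent rates: activated homomers (R'_S R'_S) raise
the activation rate k0([R'_S]), nonactivated heteromers (R_S R_L) raise the
deactivation rate k4([R_S]) — a double positive feedback loop.  At
stationarity the three core ODEs collapse to one scalar equation, a
production blade P([R'_S]) against a decay blade D([R'_S]) ("scissors"),
whose intersections are the stationary points.  At the normalised
parameter set there are five: three stable (LTD, active, LTP) separated by
two unstable points.  Transmission follows the membrane homomer pool
∝ [R'_S]², so the stable points are persistent transmission levels, and
the NSF production rate p_NSF is the bifurcation parameter that opens and
closes the LTD/LTP regimes.

Upstream, a signalling cascade maps stimulation and stress onto the core's
production rates: coincident pre/postsynaptic activity (gain σ) releases
tPA, converting proBDNF to mBDNF; cortisol C occupies MR and GR receptors
(MR = C/(C+1e-4), GR = C/(C+5)), which control TrkB and p75 expression;
mBDNF·TrkB signalling raises and proBDNF·p75 signalling lowers the
production modulation a, with p_NSF the most sensitive channel
(u_NSF = 3).  Full LTP needs the *conjunction* of coincidence (mBDNF) and
low-normal cortisol (TrkB); stress plus noncorrelated activity gives LTD.

## Worked example

```r
library(synplast)

params <- synplast_params()
find_stationary_points(params)
#> <stationary points> 5 found (3 stable) at p_NSF_eff = 1
#> # A tibble: 5 × 5
#>     RpS    RS   NSF stability label
#>   <dbl> <dbl> <dbl> <chr>     <chr>
#> 1 0.301 0.699 0.699 stable    LTD
#> 2 0.386 0.614 0.614 unstable  unlabeled
#> 3 0.5   0.5   0.5   stable    active
#> 4 0.611 0.389 0.389 unstable  unlabeled
#> 5 0.650 0.350 0.350 stable    LTP
```

Five stationary points in the pattern stable/unstable/stable/unstable/
stable: a depressed state at [R'_S] = 0.30, the active synapse at 0.50,
and a potentiated state at 0.65.  Squaring the ratios gives the
transmission levels: LTP carries 1.69× and LTD 0.36× the active-state
transmission.

```r
res <- run_scenario("fig4a")   # correlated activity, low cortisol
res
#> <scenario fig4a> fold change 2.074 (baseline 2 -> final 4.148), end state: LTP
```

The tetanus under low-normal cortisol drives the synapse into the LTP
basin; probed 5 h after preparation, the postsynaptic response is
approximately double the baseline.  The six stimulation scenarios
reproduce the full outcome table (fold change at the 5 h probe, end-state
basin):

| scenario | condition | fold | end state |
|---|---|---|---|
| fig4a | correlated, low cortisol  | 2.07 | LTP |
| fig4b | correlated, high cortisol | 1.12 | active |
| fig4c | correlated, no cortisol   | 1.05 | active |
| fig5a | noncorrelated, low cortisol  | 0.84 | active |
| fig5b | noncorrelated, high cortisol | 0.03 | LTD |
| fig5c | noncorrelated, no cortisol   | 1.00 | active |

`fig6_*`/`fig7_*` repeat the six with membrane heteromer insertion
knocked out (k11 = 0; outcomes shift by < 10 %), and `fig8_left`/
`fig8_right` are the NSF intervention protocols
(`intervention_window_scan()` maps reduction windows to end states).
Results are tibbles throughout: `tidy()` / `glance()` summarise scenario
objects, `autoplot()` draws trajectory panels and bifurcation diagrams,
and `pnsf_sweep()` exports the bifurcation table as CSV.

A thin command-line wrapper is installed at `inst/cli/synplast.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/synplast.R", package="synplast"))')" list-scenarios
Rscript .../synplast.R simulate --scenario fig4a --out out/
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch
— the stationary-point analysis, the p_NSF bifurcation sweep, and the six
stimulation scenarios — logging each result, and writes the JSON summary
to the path given by `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The model is deterministic; the seed only fixes the session state.
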