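---
title: "A bistable reaction-kinetic model of stress-dependent synaptic plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bistable reaction-kinetic model of stress-dependent synaptic plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(synplast)
```

## The model

`synplast` simulates NMDA-receptor-dependent long-term potentiation (LTP)
and depression (LTD) at a glutamatergic synapse as a deterministic
reaction-kinetic system.  Its core is the activation cycle of short-tailed
AMPA receptor subunits,

$$ R_S + NSF \;\xrightleftharpoons[k_4]{k_0}\; R'_S , $$

in which the NEM-sensitive factor (NSF) activates nonactivated subunits
$R_S$ into $R'_S$.  Neither rate is constant: activated homomeric dimers
($R'_S R'_S$) accelerate activation, so $k_0$ is an increasing, S-shaped
function of $[R'_S]$; nonactivated heteromeric dimers ($R_S R_L$, with
long-tailed subunits $R_L$) accelerate deactivation, so $k_4$ is an
increasing S-shaped function of $[R_S]$.  The two self-excitations compete —
a double positive feedback loop.  With production rates $p_\#$ and linear
decays $z_\#$ the cytosolic core is

$$
\begin{aligned}
[\dot{NSF}] &= p_{NSF} - z_{NSF}[NSF] - I, \qquad
[\dot R_S] = p_{R_S} - z_{R_S}[R_S] - I, \\
[\dot R'_S] &= -z_{R'_S}[R'_S] + I, \qquad
I = k_0([R'_S])\,[R_S][NSF] - k_4([R_S])\,[R'_S].
\end{aligned}
$$

Because the same interaction term $I$ appears in all three equations, every
stationary state satisfies a *complementary relation* that expresses
$[R_S]$ and $[NSF]$ as affine functions of $[R'_S]$, reducing the
stationary problem to one scalar equation — a nonnegative production blade
$P$ against a nonpositive decay blade $D$ (the "scissors").  With the
calibrated S-curves the blades intersect five times: three stable points
(LTD, an intermediate *active* state, LTP, in ascending $[R'_S]$) separated
by two unstable ones.  Transmission is carried by membrane receptor pools,
dominated by the homomer pool $\propto [R'_S]^2$, so the three stable
states are three persistent transmission levels and jumps between them are
synaptic plasticity.

Upstream, stimulation and stress modulate the core's production rates.
Presynaptic activity $s(t)$ releases glutamate and proBDNF; *coincident*
postsynaptic depolarisation (gain $\sigma$) releases tPA, which converts
proBDNF to mature BDNF (mBDNF).  Cortisol $C$ occupies the
mineralocorticoid and glucocorticoid receptors by Michaelis–Menten
saturation, $[MR] = C/(C + M_{MR})$ and $[GR] = C/(C + M_{GR})$ with
$M_{MR} \ll M_{GR}$; MR promotes and GR represses TrkB expression, GR
promotes p75 expression.  Activated TrkB complexes (mBDNF·TrkB) raise, and
activated p75 complexes (proBDNF·p75) lower, a production-modulation
variable $a$ that shifts $p_{NSF}$ (sensitivity $u_{NSF} = 3$) and
$p_{R_S}$ (sensitivity 1).  LTP therefore requires the *conjunction* of
coincident activity (mBDNF) and low-normal cortisol (many TrkB receptors);
stress (high GR, many p75) plus noncorrelated activity (much proBDNF)
drives LTD.

```{r equilibria}
params <- synplast_params()
find_stationary_points(params)
```

## Parameters and units

Concentrations are normalised and time is in hours.  All rates default
to 1 except the printed distinguished values: $M_{MR} = 10^{-4}$,
$M_{GR} = 5$, $u_{NSF} = 3$, $z_{tPA} = 0.5$, $z_{proBDNF} = 0.1$,
$z_{actTrkB} = z_{actp75} = 2$, $p_{BDNF} = 10$, $p_{actTrkB} = 10$,
$p_{tPA} = 2$.  The slow proBDNF decay (10 h time constant) is what makes
depression outlast the stimulus; the fast complex decays make TrkB/p75
signalling track the ligand pools.

### S-curve calibration

Only the qualitative S-shape of $k_0$ and $k_4$ is specified, so the
plateau values and ramp windows are calibration constants of this
implementation.  They were fixed once against three structural targets and
then frozen: (i) exactly five stationary points at the normalised
parameter set; (ii) a potentiated/active transmission ratio whose readout
at the 5 h probe is approximately double the baseline; (iii) a depressed
state carrying less than half the baseline transmission.  The defaults

* $k_0$: 2.4 → 6.37, ramp over $[R'_S] \in [0.58, 0.63]$,
* $k_4$: 0.2 → 2.9, ramp over $[R_S] \in [0.58, 0.66]$,

put the stable points at $[R'_S] = 0.301$ (LTD), $0.500$ (active) and
$0.650$ (LTP): equilibrium transmission ratios $({0.650}/{0.500})^2 = 1.69$
and $({0.301}/{0.500})^2 = 0.36$.  A `smooth_sigmoid` variant matched at
the plateaus is available (`scurve_shape`); the stationary structure is
unchanged, confirming that the behaviour does not hinge on the kinks.

### Bifurcation structure

Raising the NSF production rate lifts the production blade.  Sweeping it
(`pnsf_sweep()`) yields, in order: only the depressed state
($p_{NSF} \lesssim 0.83$), a tristable window containing the normalised
value 1 (≈ 0.95–1.18), and only the potentiated state
($p_{NSF} \gtrsim 1.27$).  Because the two saddle-node events on each side
of the tristable window occur at distinct parameter values, narrow
two-stable bands separate the regimes; the sweep labels them `bistable`
rather than forcing them into a three-way classification.  The hysteresis
implied by this diagram — a transient production change switches the state,
and the switch is not undone when the production returns — is the model's
memory mechanism, and is what the intervention protocols exercise.

```{r scissors, fig.height = 3}
plot_scissors(params)
```

## Stimulation scenarios and their stated world

`run_scenario()` reproduces the named simulation experiments.  Every run
starts from the same preparation: the core at the middle *active* point and
the receptor expression levels at their cortisol-conditioned steady state —
the exact fixed point that silent pre-equilibration converges to.
Transmission is probed with a standard test pulse at $t = 0.25$ h
(baseline) and $t = 5$ h (outcome); the fold change is probe-amplitude
free because the transmitted signal is linear in the pulse.

The inputs the experiments leave free were calibrated once against the
qualitative outcome table (full LTP / slight LTP / no change; small LTD /
marked LTD / no change) and then frozen:

* **Cortisol levels** — low-normal $C = 0.5$ (MR saturated, GR 9 %),
  high $C = 20$ (GR 80 %), zero $C = 0$ (the receptor-blockade condition).
  A much smaller "low" value would make the p75 channel ($\propto$ GR)
  vanish entirely and noncorrelated activity would *potentiate* through
  residual mBDNF–TrkB signalling, inverting the small-LTD outcome.
* **Correlated stimulation** — a short, sharp tetanus
  (amplitude 0.12 on $[0.5, 1.0]$ h, $\sigma = 29$), the
  high-frequency-stimulation analogue.  The brevity matters: the tPA pool
  decays with a 2 h time constant, and only a pulse-like drive lets the
  modulation $a$ cross the potentiation fold and then decay before the 5 h
  probe, so the probe reads the potentiated branch (fold ≈ 2.07) rather
  than a transient overshoot.
* **Noncorrelated stimulation** — a longer, stronger drive
  (amplitude 0.25 on $[0.5, 2.0]$ h, $\sigma = 0$), the
  low-frequency-stimulation analogue; it builds the proBDNF pool that p75
  converts into lasting depression.

Three interpretation choices are deliberately resolved against printed
formulas, each behind a switch:

* **Sign of $\dot a$** (`a_sign_convention`): the printed equation has
  activated p75 *raising* $a$ while the surrounding account (and every
  simulated outcome) has TrkB signalling raising protein production; the
  default follows the account.
* **CaMKII coincidence gating** (`camkii_coincidence_gated`): CaMKII
  activation is Ca²⁺/calmodulin-dependent downstream of the NMDA
  coincidence detector, so the default drives it with $\sigma s(t)$.  With
  the glutamate-only form, noncorrelated protocols insert membrane
  heteromers whose residue at the probe makes the $k_{11}$ knockout far
  from marginal — contradicting the knockout experiments the model itself
  reports.
* **Conservative ligand binding** (`consume_on_binding`): activated-complex
  formation consumes ligand and receptor by default.  Purely catalytic
  sensing leaves the slowly decaying proBDNF pool signalling for tens of
  hours, which converts the attenuated-LTP condition (correlated activity
  under high cortisol) into delayed LTD during settling.

One limitation is structural and left visible: at cortisol exactly zero
both occupancies vanish, the cascade is inert, and the noncorrelated
zero-cortisol scenario ends at fold 1.000 exactly — the small LTD that the
corresponding experiment reports cannot arise from these equations at
$C = 0$.  The scenario is classified `active` and sits within 0.2 of the
low-cortisol small-LTD outcome, which is the comparison the test suite
asserts.

### Classification

End states are classified by basin membership, not fold thresholds: the
full model is continued in silence until the cascade has decayed and the
core settles onto a stationary point.  The continuation matters because
production rates recover *slowly* (with the proBDNF pool); restoring them
instantaneously would re-activate a deeply depressed synapse through the
low-$k_4$ corridor and misread committed LTD as a return to the active
state.  The model's own skill-game picture — a slow change can find the
middle dimple, a rapid one cannot — is exactly this distinction.

## Numerics

The 13-species system is integrated with an embedded Dormand–Prince 5(4)
pair (PI step-size control, relative tolerance $10^{-8}$, absolute
$10^{-10}$), restarted at every waveform discontinuity so no step straddles
a jump; recorded outputs are exact solver states, never interpolants.
Stationary points are bracketed on a uniform grid (≥ 1000 cells) of the
admissible interval $[0, \min(p_{R_S}, p_{NSF})/z_{R'_S}]$ and refined by
bisection to $10^{-12}$; stability uses the analytic 3×3 Jacobian's
eigenvalues and must agree with the sign of the reduced residual's slope —
disagreement or a near-zero dominant eigenvalue raises an error rather
than silently labelling a degenerate point.  Piecewise-linear rate laws
make the right-hand side continuous but kinked; the adaptive controller
resolves the kinks by step rejection, and the smooth-sigmoid variant is
available where differentiability matters.  The model is fully
deterministic: no random numbers are drawn anywhere.

## What a green test establishes — and what it does not

The simulated experiments are *qualitative reproductions*: the stated
world (normalised rates, calibrated S-curves, calibrated protocol
constants) reproduces the direction, ordering and approximate magnitude
of the reported outcomes, including the ≈ 2× potentiation readout and the
less-than-half depression.  The model makes no claim to quantitative
agreement with measured synaptic physiology: concentrations are
normalised, the stimulus is a boxcar abstraction of a spike train, and
experimental magnitudes quoted alongside the original figures are other
laboratories' measurements, not model outputs.  Dimers stand in for
tetrameric receptors, there is no spatial structure, no stochasticity,
and GABAergic or voltage-dependent-calcium-channel plasticity is out of
scope.
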