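---
title: "Model and methods: a hybrid agent-based simulator of ATR-inhibitor response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: a hybrid agent-based simulator of ATR-inhibitor response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddrabm)
```

## The biological system and the model idea

`ddrabm` simulates populations of colon-carcinoma cells (one cell per agent in
monolayer mode, one small cell group per agent in spheroid mode) exposed to an
ATR-inhibiting drug such as AZD6738. ATR governs the intra-S checkpoint that
repairs replication-stress damage; inhibiting it converts repairable damage
into cell death. The same cell-level rule set, calibrated once against
monolayer behaviour, is reused in a spatially resolved spheroid cross-section
where oxygen and drug must diffuse to the cells — the point of the design is
exactly this monolayer-to-spheroid bridging.

Agents live on a square occupancy lattice (at most one agent per site) and
progress through a probabilistic cell-cycle graph

G1 → (S | D-S) , D-S → (S | lethal) , S → G2/M → mitosis → G1,

where D-S is the replication-stress-damaged S-phase entry state. Every agent
draws an individual doubling time `tau ~ N(mu, sigma)` (default 24 h, 0.5 h)
and spends the fraction `theta_state` of `tau` in each state (G1 11/24, S
8/24, G2/M 5/24, D-S 0.03). At G1 exit an agent enters D-S with probability
`pi_ds = 0.75`, otherwise S. An agent completing D-S repairs with probability
`1 - E(C)`, where

E(C) = Emax · C^gamma / (EC50^gamma + C^gamma)

is the sigmoid Emax effect of the local drug concentration (EC50 = 1 uM,
gamma = 2, Emax = 1: saturating drug blocks repair completely). A repair
failure is the lethal event; the agent dies `T = tau` hours later. The
narrow `sigma` makes in silico populations strongly cycle-synchronised, which
is what produces the oscillating state compositions and step-wise growth
curves seen in the readouts.

## Monolayer versus spheroid rules

| rule | monolayer | spheroid |
|---|---|---|
| agent | one cell | group of identical cells |
| daughter placement | nearest free ring, unbounded order | nearest free ring up to order 3 |
| quiescence | only when the lattice is full | no free site within Chebyshev radius 3 |
| oxygen | normoxic everywhere | reaction–diffusion field, hypoxic G1 delay |
| drug | homogeneous step at treatment, no decay | daily supply pulses outside the tumour, diffusion, 6 h half-life |
| dead cells | persist on the lattice | removed at death |

Daughters are placed by drawing Moore or von Neumann neighbourhoods with a
fair coin per division and filling the lowest non-full ring uniformly at
random, which yields compact, approximately circular colonies. When every
ring up to the placement bound is full, the parent waits at the end of G2/M
and retries — quiescence proper (G0, clock frozen, resumable) is entered from
G1 when no space is reachable.

## Transport and the hypoxia response

In spheroid mode oxygen obeys

dK/dt = div(D_K grad K) + r_K·m − phi_K·K·cell,

with supply on the boundary mask `m` (empty sites not fully enclosed by the
colony), consumption at viable-cell sites, diffusivity `2.5e-5 cm^2/s`
divided by 1.5 inside the colony, and zero-flux boundaries. Oxygen is
rescaled at every evaluation to percentages of its current maximum (`h =
100`); sites at or below 10 % are hypoxic. Hypoxia elongates G1 by the delay
factor `G1DF` (2 below 1 %, `0.9209 + 0.82/(−0.2389 + K̂)` on [1, 10.5] %, 1
above); the G1 clock accumulates `dt / G1DF` so an agent moving through
changing oxygen experiences a path-dependent G1.

The drug field follows the same transport form with supply applied at
boundary-mask sites during a 1 h window once daily, first-order elimination
matched to the 6 h in vivo half-life, and a diffusivity scaled from oxygen by
the square root of the molecular-weight ratio, `sqrt(31.998/412.512) ≈
0.27851`. The intracellular slowdown is applied to the drug too by default
(`slow_drug_in_cells`), since the transport coefficient is written as
space-dependent; this is switchable.

## Numerics

* **Scheme.** Explicit conservative flux-form finite differences with
  harmonic-mean interface diffusivities (the standard conservative choice for
  discontinuous coefficients) and mirror boundaries. Substeps obey the
  stability bound `dx^2/(4 max D)` with a 0.9 safety factor plus an accuracy
  cap `sink·dt ≤ 1e-3`, so first-order decay is resolved to better than 0.1 %
  over a half-life. Without sources and sinks the scheme conserves mass to
  rounding error and converges at second order against the 2-D heat kernel.
* **Quasi-steady oxygen.** Oxygen transport equilibrates orders of magnitude
  faster than cell dynamics (stability substep ~0.13 s at 40 um spacing
  versus the 0.1 h agent step), so the oxygen field is kept at its
  quasi-steady profile rather than co-integrated in real time: a direct
  sparse solve of the *same* discrete steady-state system anchors the field
  at initialisation and every `steady_solve_every` agent steps, with explicit
  relaxation substeps (budget `field_substeps`, tolerance 1e-6 per substep)
  tracking it in between. Cold-start explicit relaxation alone would need
  upward of 1e5 substeps on a 200 x 200 grid because the homogeneous Neumann
  mass mode converges at the domain-diffusion timescale.
* **Drug in real time.** Drug dynamics (daily pulses, 6 h half-life) are
  genuinely transient and are co-integrated with explicit substeps over each
  agent step.
* **Time discretisation.** Agents update on a fixed `dt = 0.1 h`, which
  resolves the shortest phase (`theta_ds·tau ≈ 0.72 h`). Phase-completion
  overshoot is carried into the next phase, so the realised time per phase is
  exact to within one `dt`; the only systematic loss is the parent's G2/M
  overshoot at division (≤ `dt`, ~0.2 % of a cycle). Agents are updated
  vectorised; division events are resolved in randomly permuted order each
  step to avoid lattice-scan anisotropy.
* **Determinism.** All randomness flows from one seed per replicate
  (replicate `i` of an experiment uses `seed + i − 1`); identical
  configuration and seed reproduce results bit for bit.

## Chosen defaults where the source material leaves freedom

These choices were made once, from the physics or biology of the system, and
are exposed as parameters rather than revisited:

* **`r_k = 1, phi_k = 0.02 /s`.** The supply and consumption coefficients are
  not printed anywhere; the scaled oxygen field is exactly invariant to
  `r_k`, and `phi_k = 0.02 /s` sets the oxygen consumption length
  `sqrt(D_in/phi_k) ≈ 290 um` (7 lattice sites), inside the 100–300 um
  hypoxia-depth range reported for avascular tumour tissue. Colonies beyond
  ~25 sites radius then develop a sub-10 % core.
* **`dose_to_supply = 0.15 uM/h per mg/kg`.** The mapping from a dose label
  to a supply amplitude stands in for a bioavailability calibration that is
  not reproducible from printed values. The coefficient is set so the 25 and
  50 mg/kg doses produce rim concentrations bracketing EC50 = 1 uM (peaks of
  a few uM decaying at the 6 h half-life), i.e. the tested doses span the
  informative part of the Emax curve.
* **D-S time is additional to S.** A repaired agent spends the full
  `theta_s·tau` in S after its `theta_ds·tau` in D-S; the damage fraction is
  fitted separately from the S fraction, and the ~3 % cycle lengthening is
  small against `sigma`. A drug-free damage-routed cycle therefore lasts
  `(1 + theta_ds)·tau` (24.72 h at `tau = 24`).
* **gammaH2AX numerator and denominator.** Damaged cells are D-S residents
  *plus* repair-failed agents awaiting death: a cell that cannot repair keeps
  its damage marker until it dies. The denominator excludes dead cells by
  default (assays gate on intact cells). The all-agents denominator is
  available as a configuration switch, but with it the asymptotic damage
  fraction stops being monotone in dose — accumulating corpses swamp the
  denominator at high dose — contradicting the dose-ordered response curves
  the model is meant to reproduce.
* **Quiescence scan.** The space check uses the union of Moore and von
  Neumann neighbourhoods through the placement bound, which equals the
  Chebyshev ball — the most permissive reading.
* **G0 semantics.** Quiescent agents keep their G1 clock and resume, not
  restart; resumption is the minimal interpretation of re-entry.
* **Daughters draw fresh doubling times; parents keep theirs**, maintaining
  the population distribution without inheritance assumptions.
* **Spheroid treatment trigger 0.25 cm^3**, the midpoint of the 0.2–0.3 cm^3
  in vivo treatment-start range.
* **Output cadence** 1 h (monolayer) and 6 h (spheroid): resolves the ~24 h
  state-composition oscillations and the daily dosing, respectively.

## What the simulations emulate — and what they do not

The monolayer generator reproduces the study conditions of the in vitro
experiments: growth from a single founder to ~1000 cells, an instantaneous
homogeneous drug step at treatment, 72 h of follow-up, readouts as
gammaH2AX-positive percentage and total cell count, and replicate means and
standard deviations (100 replicates by convention; property checks in the
test-suite run 25). The spheroid generator reproduces a 2-D cross-section
with 40 um spacing, daily dosing for 14 days and disc-to-sphere extrapolated
volume, `V = (4/3)·pi·(A/pi)^{3/2}` from the occupied area `A`.

Real cell populations are not this clean: the model has no angiogenesis,
immune or stromal compartment, no pharmacokinetic compartments or receptor
dynamics, no drug resistance, and its rules and parameters do not adapt over
time — which is precisely why late-time tumour data (beyond ~8 days) drift
away from simulations of this family. Passing tests therefore demonstrate
internal correctness and the qualitative response structure (dose-ordered
damage, hypoxic quiescent cores, drug gradients, volume suppression), not
predictive accuracy for any particular cell line beyond the calibrated one.

The test-suite exercises the spheroid mode at desk scale (lattices of 60–200
sites, trigger volumes of 2.5e-4 to 3e-3 cm^3, three daily doses, 72 h
follow-up). The full-scale configuration — 1000 x 1000 lattice, 0.25 cm^3
trigger, 14 daily doses, 100 replicates — is what
`simulation_config("spheroid")` produces by default; a single replicate of it
is an overnight single-machine job and is not part of any test.

## Degenerate inputs and edge behaviour

* An all-zero oxygen field scales to zero with a warning (no division by a
  zero maximum).
* An empty population makes the gammaH2AX fraction undefined; it is reported
  as missing with a warning.
* A monolayer division with no free site anywhere on the lattice aborts with
  a diagnostic — it means the lattice was configured too small for the
  requested experiment.
* Doubling-time draws reject non-positive values; at the default `mu/sigma`
  the rejection probability is ~1e-500, so the moments are unaffected.
* Field updates abort on non-finite values and on negative values beyond
  rounding tolerance rather than silently clamping.

## Known limitations

* The steady-oxygen anchor solves the discrete steady state exactly, but
  between anchors the explicit relaxation budget (`field_substeps`) limits
  how fast the profile tracks colony growth; for very fast-growing colonies
  increase the budget or `steady_solve_every` frequency.
* Monolayer mode deliberately ignores spatial heterogeneity (unbounded
  placement order, homogeneous drug), so positions carry no information
  there.
* The disc-to-sphere volume extrapolation is isolated in `spheroid_volume()`
  so an alternative stereological rule can be swapped in.
* One agent step resolves at most one phase transition; this is safe for
  `dt` well below `theta_ds·mu` (the default 0.1 h is seven times smaller)
  but a user-supplied `dt` approaching the shortest phase would coarsen
  transition timing.
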