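---
title: "The stromasim multiscale model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The stromasim multiscale model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

stromasim simulates how cancer-associated fibroblasts (CAFs) push cancer
cells toward an invasive phenotype, across three coupled levels of
description: biochemical signaling inside each cell, diffusing signals in
a three-dimensional tumor microenvironment (TME), and force-based motion
of individual cells. This vignette explains the model, the parameters
that matter, the numerical choices, and what the package's tests do and
do not establish.

## Intracellular level: two reaction networks

Each cell carries its own copy of a nonlinear ODE system derived from
mass-action and saturating (Michaelis–Menten type) rate laws.

**Cancer cell (21 states).** The TGF-β arm follows the canonical SMAD
cascade: ligand–receptor association (with squared receptor kinetics,
`k2p * TGFb * TGFbR^2`, consuming two receptors and one ligand per
complex), SMAD3 phosphorylation saturating in SMAD3
(`k5p * complex * x3/(x3 + Ks1)`), pSMAD3–SMAD4 complex formation,
nuclear shuttling, and transcription of the target genes SMAD7 (negative
feedback), TGF-β itself (autocrine drive), LIF, and CXCR4. The CXCL12 arm
— CXCL12·CXCR4 association, PI3K/Akt phosphorylation relay, NF-κB
activation, and MMP production/secretion — is not published as a rate
table; we reconstructed it in the same idiom (association/dissociation
pairs, saturating phosphorylation steps, first-order turnover) and flag
every such reaction `provenance = "reconstructed"` in the network objects
and the shipped JSON definitions.

**CAF (26 states).** The LIF/JAK/STAT arm is taken row-by-row from the
published table: paracrine and autocrine LIF binding (two routes sharing
one printed label), JAK and STAT phosphorylation, nuclear import, STAT
acetylation, SOCS3 and SHP1 negative regulation, and the
pSMAD3–pSTAT crosstalk complex whose nuclear form transcribes SNAIL. The
TGF-β/SMAD mirror feeding pSMAD3 and the CXCL12/TGF-β target genes is
reconstructed as in the cancer cell. Two further species are needed to
reach the published state count of 26; we chose a pair of cytoplasmic
inhibitory complexes (SMAD7 bound to the receptor, and to pSMAD3) — a
mechanistically motivated guess, flagged as reconstruction, not asserted
as the original composition.

Three conventions worth knowing:

* **Production terms are kept as printed**, including forms proportional
  to their own product (e.g. receptor production `k1p * x1`), which makes
  pools capable of exponential autogrowth. A `constitutive_production`
  switch replaces these with zero-order sources for exploratory use;
  it defaults to off.
* **Inhibitory rows** ("inhibitory effect of A on B", rate proportional
  to A only) are realized as extra first-order removal fluxes on B.
* **Observable map.** Measured genes are SMAD7, TGF-β, LIF and CXCL12,
  reported as fold changes relative to t = 0. The 21-state cancer network
  has no dynamical CXCL12 species (CXCL12 reaches the cancer cell only as
  an external input), so the CXCL12 readout of the cancer model is mapped
  to CXCR4 — the printed CXCL12-axis target gene of the TGF-β pathway — as
  a proxy. The CAF map is direct (SMAD7, secreted TGF-β, autocrine LIF,
  secreted CXCL12).

**Default parameters.** No calibrated values are published for most
constants. Our versioned defaults start from a flat baseline (0.1 h⁻¹
rate constants, 1.0 a.u. half-constants, species at 1.0 a.u. with
complexes at 0) and adjust about thirty constants so the stimulated
networks behave like stimulated cells rather than draining away:
receptor/substrate synthesis slightly exceeds turnover (binding would
otherwise exhaust the pools), activation steps are an order of magnitude
faster than baseline, and target-gene production outweighs decay. Under
these defaults all four measured genes rise above baseline within 48 h
in both cell types — the qualitative behavior expected of the stimulated
co-culture — while every state stays finite and nonnegative over 72 h.
These are placeholders to be refined by estimation, not biological
claims.

```{r}
library(stromasim)
spec <- build_cancer_cell_network()
traj <- simulate_network(spec$network, inputs = c(xu3 = 1, xu4 = 1),
                         times = seq(0, 72, by = 2))
observables(spec, traj)   # gene x time fold changes at 0/24/48/72 h
```

**Numerical choices.** Trajectories are integrated with `deSolve::lsoda`
and floored at zero below 1e-12. `evaluate_rate()` reproduces every
printed formula exactly; at assembly time each flux is additionally
scaled by a smooth availability factor `x/(x + 1e-6)` for any species it
consumes that does not appear in its own rate law. Only the inhibitory
removal rows qualify; without the factor they keep withdrawing from an
already-empty pool, and the resulting hard nonnegativity guard makes the
stiff integrator chatter at the zero boundary. The factor is negligible
(relative effect below 1e-6) whenever the pool holds more than ~1e-6 a.u.

## Estimation: hybrid unscented Kalman filtering

Sparse four-point expression time courses cannot support gradient-based
fitting of dozens of constants, so the package uses a continuous-discrete
("hybrid") unscented Kalman filter: sigma points of the augmented state
(species concentrations plus *logarithms* of the free parameters, so
estimates are positive by construction) are propagated through the full
nonlinear ODE between measurement times and corrected with the
fold-change observable map (model observable divided by its t = 0
value). Parameters follow a random walk with small process noise;
`n_passes` repeated sweeps over the same short time course re-initialize
the states but carry the parameter statistics, mimicking iterated
refiltering. Defaults: α = 1e-3, β = 2, κ = 0, state process noise
1e-6/h, log-parameter process noise 1e-4/h, 10 passes.

Design notes:

* Moments of transformed sigma points are accumulated in deviation form
  around the central point; with α = 1e-3 the weights are ~1e5 of mixed
  sign and the naive weighted sum loses five digits to cancellation.
* The covariance is symmetrized with an eigenvalue floor of 1e-12 after
  every correction; a sigma point whose ODE propagation fails is replaced
  by the prior mean with a warning.
* On a linear-Gaussian system the filter collapses to the classical
  Kalman recursion; the test suite checks agreement with an
  independently coded discrete filter to 1e-6.
* The synthetic recovery experiment (five free parameters perturbed by
  U(0.5, 2), four observation times, 5% multiplicative noise, ten
  passes) uses the per-gene production constants plus one decay constant
  — a deliberately identifiable set; strongly collinear sets (e.g. the
  shared upstream phosphorylation constant together with all four
  production constants) recover the response surface but not the
  individual values, which is an identifiability limit of four-point
  single-condition data, not of the filter.

Morris elementary-effects screening complements the filter: effects are
computed in raw parameter units (`EE_i = (y(θ+Δe_i) − y(θ))/Δ_i`), so a
linear response yields `mu = coefficients` exactly; `mu_star` ranks
overall importance and `sigma` flags nonlinearity/interaction. Fit
quality is summarized by R², RMSE, MAE and Bland–Altman limits of
agreement (bias ± 1.96 sd of differences).

## Intercellular level: fields in a spherical TME

The TME is a sphere of radius 2 cm. Each communicating signal (cancer
TGF-β and LIF; CAF TGF-β and CXCL12), SNAIL and MMP is a concentration
field obeying `∂u/∂t = D Δu − f(u)`, with `f` realized as first-order
decay plus cell-mediated uptake (both individually switchable); SNAIL
diffuses without reaction. The original formulation used finite elements
on ~1000 subdomains; we discretize instead on a regular Cartesian grid
(default 33³) with a sphere mask and explicit finite differences — an
equivalent-in-the-limit substitution that is directly testable against
the analytic eigenmodes of the ball.

* **Boundary.** The Dirichlet far-field value (default 0, absorbing) is
  held on the first layer of nodes *outside* the sphere. The staircase
  boundary shifts the effective radius by about half a grid spacing;
  measured on the 33³ grid the fundamental mode decays about 3% slower
  than the analytic rate Dπ²/R², comfortably within the 5% tolerance the
  tests enforce. Pinning the innermost inside layer instead would bias
  the rate ~7% fast, which is why the outside convention was chosen.
* **Stability.** Explicit steps require `D·dt/h² ≤ 1/6`; `diffuse()`
  sub-steps automatically, `step_diffusion()` refuses an unstable step
  and names the required sub-step count.
* **Coupling.** Cell-surface signal levels are computed by a 26-direction
  symmetric quadrature of the field over the cell sphere (exact for
  uniform fields; odd linear terms cancel by symmetry). Secretion enters
  as trilinear point sources conserving deposited mass to 1e-12. The
  intracellular external input is the *mean surface concentration*
  (surface integral divided by 4πR²), times a configurable
  `input_scale`; thresholds are expressed in the same unit.
* **Units.** The grid is in cm, cells in µm; conversions go through
  `um_to_cm()`/`cm_to_um()` only.
* **ECM.** `d[ECM]/dt = a1[ECM] − a2[MMP][ECM]` per node, forward-Euler
  sub-stepped at ≤ 0.5 h, floored at zero. Defaults a1 = 0 (no net
  regrowth over a 72 h experiment), a2 = 0.02 per a.u. per h.
* The diffusion coefficients default to 3.6e-3 cm²/h (1e-6 cm²/s), an
  order-of-magnitude placeholder for small secreted proteins in tissue,
  marked as such in the configuration.

## Population level: states, forces, motion

Every macro-step each cancer cell reads its surface CXCL12 and SNAIL and
the local ECM, then decides its state. The published decision diagram
does not fix the branch order textually; we check **migration first**
(SNAIL ≥ T_SNAIL *and* ECM ≤ T_ECM), then proliferation (CXCL12 ≥
T_CXCL12), else quiescence — migration being the terminal phenotype of
interest. Raising SNAIL can therefore never demote a migratory cell, a
property the tests enforce.

Forces on a cell (all applied at the center, CAFs and non-migratory
cells never move):

| force | form | notes |
|---|---|---|
| repulsion | `(4/3) Ê √R̂ δ^{3/2}` | Hertz contact, overlap δ > 0 |
| adhesion | `π W R̂` | constant magnitude within ±2 µm of contact |
| haptotaxis | `−χ ∇[ECM]` | sign as printed: down-gradient for χ > 0 |
| active | `η A^n/(A^n + A0^n) n̂` | A = surface SNAIL |
| friction | `−Γ^cs V` | sets `V = ΣF / Γ^cs` |

The printed haptotaxis sign (down-gradient) is kept even though
haptotaxis is conventionally up-gradient toward adhesive substrate; in
this model MMP-degraded ECM around the tumor makes the printed sign the
one that drives outward invasion, and χ may be set negative in the
configuration to explore the conventional reading. The active-force
direction n̂ is not specified in the source; the default is the outward
unit vector from the population centroid (invasion away from the tumor
core), with `down_ecm` and `random` as alternatives. Adhesion is printed
as a scalar; we realize it as a constant-magnitude central attraction
within a 2 µm gap of contact. Proliferative cells divide once per 24 h,
placing a quiescent daughter one radius away in a uniformly random
direction.

## The macro-loop and its two clocks

Within a step the stage order is fixed (it is not fully specified by the
source): intracellular chemistry with surface inputs → secretion
deposits → diffusion → ECM update → classification → division → forces
and motion; end-of-step values seed the next step. The original
describes a 0.05 s repetition interval yet reports biology over 72 h; we
therefore keep two clocks — `hours_per_step` (default 7.2 h, so ten
macro-steps span the 72 h experiment) for the biology, and the fast
mechanical sub-step `Ts` retained as a configuration preset. Diffusion
is always sub-stepped to its stability bound regardless of either clock.

Default scenario: 20 cancer cells and 20 CAFs placed uniformly at random
(rejection sampling, no pair overlapping by more than half their summed
radii, whole cells kept inside the domain) in the 2 cm sphere; all
cancer cells start quiescent; fields start at configured constants (ECM
at 1, signals at 0). `migration_preset()` lowers the thresholds to
values the default secretion levels actually cross, which is the setting
used to study the displacement trend; with thresholds at their
conservative defaults or +∞ a run provably changes nothing, and the
tests check both regimes. Reproducibility is strict: the random-stream
state lives inside the `SimulationState`, so identical config+seed give
byte-identical outputs and a run interrupted and resumed equals the
uninterrupted run exactly.

## Synthetic data: what it emulates and what it does not

`generate_timecourse()` emulates sparse public four-point (0/24/48/72 h)
fold-change expression series of SMAD7, TGF-β, LIF and CXCL12 under
constant stimulation: the model is simulated, mapped to fold changes,
and multiplied by log-normal noise (default sd 5%, multiplicative
because expression data are ratio-scaled), with t = 0 re-anchored to 1.
It does not emulate microarray platform or probe effects, batch
structure, biological replicate dispersion, or cross-condition designs.
Consequently, passing the recovery tests shows that the estimation
machinery is *correct and well-conditioned on data of this shape*; it
does not show that the defaults describe any particular cell line, nor
that parameters of the full networks are identifiable from real series
with unknown normalization.

## Problem sizes used by the tests

The suite runs the micro-scale fixtures everywhere except: the eigenmode
check (33³ grid, 600 explicit steps), the recovery experiment (five free
parameters, 53 sigma points × 3 intervals × 10 passes), and the
displacement-trend run (full default scenario: 33³ grid, 40 cells, 10
macro-steps). These sizes were chosen as the smallest that exercise the
claims at full fidelity; all other tests use 11³–17³ grids and 6–8
cells.

## Known limitations

* The reconstructed CXCL12 cascade and the two extra CAF species are
  plausible but unverifiable against the unpublished full listing.
* Self-proportional production terms make long-horizon (≫ 72 h)
  simulations grow without bound; the model is meant for the 72 h
  experimental window.
* No cell death, CAF motility, contact inhibition, or volume exclusion
  beyond pairwise Hertz contact; no stochastic (Gillespie) chemistry; no
  SBML interchange.
* Thresholds, mechanical constants and diffusion coefficients are
  order-of-magnitude placeholders; quantitative displacement values are
  therefore configuration-dependent, and only the qualitative trend
  (strictly increasing mean displacement once migration is enabled) is a
  claim of the package.
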