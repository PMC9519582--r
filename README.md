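# stromasim

Multiscale simulation of tumor–stromal interaction: how cancer-associated
fibroblasts (CAFs) drive cancer cells toward proliferation and migration.
The package is aimed at systems-biology modelers who want a tested,
fully reproducible reimplementation of the three-level picture —
intracellular signaling, diffusing intercellular signals, and force-based
cell motion — together with the estimation machinery (unscented Kalman
filtering, Morris screening, fit/agreement statistics) needed to
confront such models with sparse expression time courses.

## The model

**Molecular level.** Two nonlinear ODE reaction networks built from
mass-action and saturating rate laws:

* cancer cell (21 states): TGF-β/SMAD signaling with SMAD7 negative
  feedback and target genes TGF-β, LIF, CXCR4, coupled to a
  CXCL12–CXCR4 → PI3K/Akt → NF-κB → MMP cascade;
* CAF (26 states): a TGF-β/SMAD mirror plus LIF → JAK/STAT signaling
  with SOCS3/SHP1 feedback and the pSMAD3–pSTAT complex that drives
  SNAIL.

Rate laws follow the published tables row by row, e.g. SMAD3
phosphorylation `v9 = k5+ · x2 · x3/(x3 + Ks1)`; reconstructed reactions
(the unpublished CXCL12 cascade and two CAF species) are flagged
`provenance = "reconstructed"`.

**Cellular level.** Secreted signals (TGF-β, LIF, CXCL12, SNAIL, MMP)
diffuse through a 2 cm spherical microenvironment,

∂u/∂t = D Δu − f(u),   Dirichlet far field,

on a 33³ masked Cartesian grid; cells couple to the fields by
surface-integral uptake (`ū = ∫_A u ds`, 26-point symmetric quadrature)
and point-source secretion, and the ECM obeys
`d[ECM]/dt = a1[ECM] − a2[MMP][ECM]`.

**Population level.** Each cancer cell is classified every macro-step
(migratory if surface SNAIL ≥ T_SNAIL and local ECM ≤ T_ECM, else
proliferative if CXCL12 ≥ T_CXCL12, else quiescent) and migratory cells
move by the overdamped force balance

F_rep + F_adh + F_hap + F_act = Γ^cs V,

with Hertz repulsion `(4/3)Ê√R̂ δ^{3/2}`, constant adhesion `πWR̂`,
haptotaxis `−χ∇[ECM]`, and a SNAIL-saturating active force
`η A^n/(A^n+A0^n) n̂`.

**Estimation.** Unknown kinetic constants are estimated from 4-point
fold-change time courses with a continuous-discrete (hybrid) unscented
Kalman filter on the log-parameter–augmented state; Morris
elementary-effects screening ranks parameter influence; R²/RMSE/MAE and
Bland–Altman limits of agreement quantify fit.

See `vignettes/multiscale-model.Rmd` for assumptions, defaults, and
numerical choices.

## Worked example

```r
library(stromasim)

# 1. simulate the stimulated cancer-cell network and read off the genes
spec <- build_cancer_cell_network()
traj <- simulate_network(spec$network, inputs = c(xu3 = 1, xu4 = 1),
                         times = seq(0, 72, by = 2))
round(observables(spec, traj), 3)
#>        0    24    48    72
#> SMAD7  1 7.902 5.961 2.771
#> TGFb   1 6.836 4.005 0.549
#> LIF    1 7.902 5.961 2.771
#> CXCL12 1 5.493 4.715 3.156
```

All four measured genes rise well above their t = 0 baseline within
24–48 h of stimulation — the qualitative signature of a cancer cell
conditioned by CAF-derived TGF-β and CXCL12 — before relaxing as the
negative feedbacks engage.

```r
# 2. recover perturbed parameters from noisy synthetic observations
free  <- c("k8p", "k9p", "k10p", "k11p", "k8m")
obs   <- generate_timecourse(spec, noise_sd = 0.05, seed = 11)
start <- perturbed_truth(spec, c(0.5, 2), seed = 12, parameters = free)
cfg   <- filter_config(free_parameters = free, n_passes = 10,
                       measurement_noise = 0.05^2)
res   <- hukf_estimate(spec, obs, cfg, initial_parameters = start)
median(abs(res$estimated_parameters - spec$network$parameters[free]) /
       spec$network$parameters[free])
#> [1] 0.0864
```

Starting from parameters mis-scaled by up to 2x, ten filtering passes
over a single noisy 4-point time course bring the median relative error
down to about 9%.

```r
# 3. a full multiscale run: 20 cancer cells + 20 CAFs, 10 macro-steps
run <- run_simulation(migration_preset(seed = 7))
mean_displacement(run$history, c(24, 48, 72))
#>   time_h mean_displacement_mm
#> 1     24            0.135
#> 2     48            0.322
#> 3     72            0.519
```

Once CAF-secreted SNAIL accumulates and MMP degrades the local ECM,
cancer cells switch to the migratory state and the population's mean
displacement increases strictly with time — the qualitative trend seen
in wound-scratch migration assays, at the sub-millimeter scale.

A thin command-line front end over the same functions is installed at
`inst/cli/stromasim.R` (`simulate`, `estimate`, `sensitivity`,
`list-reactions`, `init-config`).

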