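# sirspread

Agent-based **S**usceptible–**I**nfected–**R**emoved modeling of prion-like
protein propagation on weighted, spatially embedded brain networks — with
normative W-score morphometry, simulated-vs-observed peak-fit analysis, and
connectome/expression null models.

## The scientific problem

In Parkinson's disease (and several other neurodegenerative conditions),
misfolded alpha-synuclein is thought to spread trans-neuronally in a
prion-like fashion: pathological conformers template the misfolding of
normal protein and travel along white-matter connections, and atrophy
follows the accumulating pathology. `sirspread` is for researchers who want
to test that hypothesis computationally: simulate where pathology *should*
go given a structural connectome and regional gene expression, compare the
simulated atrophy pattern with longitudinal atrophy measured in patients,
and ask — with matched null models — which ingredients (network topology,
geometry, synthesis gene, clearance gene) the agreement actually depends on.

## The model

Protein molecules are agents in three compartments: susceptible (normal),
infected (misfolded), removed (degraded). Per region *i* with size *S_i*,
each timestep Δt applies:

* synthesis: `+ α_i · S_i · Δt` susceptible agents, `α_i = Φ(SNCA_i)`;
* clearance: both populations lose the fraction `1 − exp(−β_i Δt)`,
  `β_i = Φ(GBA_i)`;
* misfolding: surviving susceptibles convert with probability
  `1 − exp(−M_i Δt / S_i)`;
* mobility: regions keep fraction `ρ_i` per unit time and route outflow into
  edges ∝ `w_ij / Σ_j w_ij`; an edge of length `l_ij` delivers the fraction
  `min(1, v·Δt / l_ij)` of its in-transit content per step;
* atrophy: `ΔL_i = k1 (1 − e^{−r_i(t)}) Δt + k2 Σ_j (w_ji/Σ_j w_ji)
  (1 − e^{−r_j(t−1)}) Δt`, with `r_i = M_i/(N_i+M_i)` — direct toxicity plus
  deafferentation.

Observed atrophy enters as age/sex-adjusted W-scores
(`(raw − predicted) / SD_resid`, normative OLS on controls) differenced
between timepoints into progression maps. The model fit is the **peak
Spearman correlation** between simulated atrophy across timesteps and the
observed map, tested against rewired (topology), repositioned (geometry),
gene-shuffle and spatial-autocorrelation-preserving surrogate nulls.

See `vignettes/sir-spreading-model.Rmd` for the full treatment.

## Worked example

Everything below runs on synthetic data generated by the package itself; no
external files are needed.

```r
library(sirspread)

spec <- synth_spec()                         # 42 regions, PD-scale cohort
cn   <- make_connectome(spec, seed = 1)
expr <- make_expression(spec, cn, seed = 2)
rates <- expression_to_rates(expr)           # alpha, beta = Phi(z-scored expr)
cn
#> <connectome> 42 regions, 301 undirected edges (density 0.350)

cfg  <- sir_config(n_steps = 2000, seed_region = "roi_01")
traj <- sir_simulate(cn, rates, cfg)         # burn-in, inject, iterate
traj
#> <atrophy_trajectory> 2000 steps x 42 regions (burn-in 1 steps)
#>   final infected fraction: 0.1623 (min) .. 0.9676 (max)

# a longitudinal cohort carrying the simulated atrophy signal
made <- make_cohort(spec, cn, traj, seed = 3)
nm   <- fit_normative(made$cohort)           # OLS on the 157 controls
ws   <- cohort_wscores(made$cohort, nm)
pm   <- progression_map(wscore_map(ws, "baseline"), wscore_map(ws, "year1"))

fit <- correlation_curve(traj, pm, seed = 9)
fit
#> <sir_fit> peak Spearman rho = 0.974 at step 1051 (p = 2.83e-27,
#>   search-corrected p = 0.002) over 2000 steps, 42 regions
```

The peak fit of 0.974 at step 1051 says the simulated atrophy pattern at
that timestep rank-matches the observed 1-year progression map almost
perfectly — expected here, since the cohort was built from the trajectory.
The search-corrected p (0.002 at 500 label permutations) accounts for the
peak being selected over all timesteps; the nominal p does not.

Null models ask what the fit depends on:

```r
np <- null_peaks(cn, expr, pm, cfg, kind = "rewired", reps = 100, seed = 4)
null_significance(fit, np)
#> <null_distribution> rewired: true peak 0.974 vs 100 nulls (mean 0.801);
#>   t = -42.34, p = 3.15e-65; exceedance 0.000
```

Rewiring the connectome (degrees and weight multiset preserved) drops the
best achievable fit to ~0.80 and the true peak beats all 100 draws: on this
system the fit genuinely depends on the network's topology. `autoplot()`
methods plot trajectories, fit curves and null distributions; `tidy()` /
`glance()` return tibbles.

A thin command-line front-end over the same functions is included at
`inst/cli/sirspread.R` with `synth`, `simulate`, `fit` and `nulls`
subcommands.

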