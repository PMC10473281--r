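---
title: "An agent-based SIR model of prion-like protein spread and atrophy on brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based SIR model of prion-like protein spread and atrophy on brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirspread)
```

## The model

`sirspread` simulates the propagation of a pathogenic, prion-like protein —
the motivating case is misfolded alpha-synuclein in Parkinson's disease —
over a weighted, spatially embedded brain network, and the atrophy that
accrues as pathology accumulates. Protein molecules are agents in one of
three compartments: *susceptible* (normal protein), *infected* (misfolded
protein), and *removed* (degraded or exited). The implementation is a
deterministic mean-field one: the update equations are expected-value
population increments, so populations are continuous nonnegative reals and a
run is exactly reproducible from its inputs.

Each region $i$ of the network has a size $S_i$ (voxel count), a 3-D
centroid, a synthesis-gene expression value (SNCA, which scales production
of normal protein) and a clearance-gene expression value (GBA, which scales
degradation of both species). Regions are joined by undirected edges with
connection strengths $w_{ij}$ and physical lengths $l_{ij}$ (mm). Agents in
transit live *in* the edges, so long tracts impose real transport delays.

Five processes define one timestep of length $\Delta t$:

1. **Synthesis.** Region $i$ gains $\alpha_i S_i \Delta t$ susceptible
   agents, with $\alpha_i = \Phi(\text{SNCA}_i)$, $\Phi$ the standard normal
   CDF.
2. **Clearance.** A fraction $1 - e^{-\beta_i \Delta t}$ of both regional
   populations is removed, with $\beta_i = \Phi(\text{GBA}_i)$.
3. **Misfolding.** Of the susceptible agents surviving clearance, a fraction
   $1 - e^{-\gamma_i^0 M_i \Delta t}$ becomes infected, where
   $M_i$ is the start-of-step infected population and
   $\gamma_i^0 = 1/S_i$ is the per-encounter misfolding likelihood: in a
   larger region a single misfolded agent meets any given susceptible agent
   less often.
4. **Mobility.** Each region retains the fraction $\rho_i$ per unit time
   (exit fraction $(1-\rho_i)\Delta t$) and distributes its outflow into
   edges in proportion to $w_{ij} / \sum_j w_{ij}$; each edge delivers the
   fraction $\min(1,\, v\,\Delta t / l_{ij})$ of its content into its target
   region, where $v$ is the propagation speed. Agents in transit are exempt
   from clearance and misfolding.
5. **Atrophy accrual.** Region $i$ accrues
   $\Delta L_i(t) = k_1\,(1 - e^{-r_i(t)})\,\Delta t +
   k_2 \sum_j \frac{w_{ji}}{\sum_j w_{ji}} (1 - e^{-r_j(t-1)})\,\Delta t$,
   where $r_i(t) = M_i/(N_i + M_i)$ is the infected fraction. The first term
   is direct toxicity; the second is deafferentation — damage inherited from
   afferent neighbours, weighted by their normalised input strength. Both
   terms are bounded by $k\,\Delta t$, so with $k_1 = k_2$ they have equal
   maximal effect.

A run consists of a **burn-in** (the infection-free system is brought to its
synthesis–clearance equilibrium), an **injection** of misfolded mass into a
seed region (the substantia nigra in the Parkinson's application), and
`n_steps` recorded iterations.

### Order of operations within a step

The increment algebra of the model applies every loss term to the
start-of-step population and adds synthesis as an independent term; an
operational step order must be fixed to make that algebra exact and to keep
populations nonnegative for any admissible parameters. `sirspread` applies
clearance → misfolding → mobility → synthesis. Two consequences are used as
analytic anchors in the test suite: an isolated region's susceptible
population converges to $N^* = \alpha S \Delta t / (1 - e^{-\beta\Delta t})$,
and with synthesis off its infected population decays exactly as
$M(t) = M(0)\, e^{-\beta \Delta t\, t}$. Because all per-step transition
fractions lie in $[0,1]$ by construction, populations cannot go negative,
and the total population changes each step by exactly synthesis − clearance
(+ injection), which the suite asserts to $10^{-9}$ relative over
1,000-step runs.

### Burn-in

The infection-free dynamics are linear in the populations, so the
equilibrium solves a small linear system (one balance equation per region;
edge loads follow from inflow = delivery). `sir_burn_in()` starts at that
solution by default and certifies it by iterating until the largest relative
change of any regional susceptible population over one step falls below
`burn_in_tol` ($10^{-7}$ by default); `init = "empty"` instead relaxes from
zero populations, which is slower but useful for studying convergence
itself.

## Tunable parameters

| parameter | default | units / range | meaning |
|---|---|---|---|
| `dt` | 0.1 | model time, (0, 1] | step length; peak fits are stable for 0.1–0.9 |
| `rho` | 0.5 | probability, [0, 1] | per-region retention per unit time |
| `v` | 1 | speed multiplier, > 0 | scales edge exit probability $v\Delta t/l_{ij}$ |
| `n_steps` | 10,000 | steps | recorded post-injection iterations |
| `injection` | 1 | agents | misfolded mass placed in the seed; downstream comparisons are rank-based, so the amount is not critical |
| `k1`, `k2` | 0.5, 0.5 | weight, ≥ 0 | toxicity and deafferentation weights |
| `burn_in_tol` | 1e-7 | relative change | equilibrium declaration threshold |

Expression is z-scored across regions before $\Phi$ by default
(`standardize = TRUE` in `expression_to_rates()`): $\Phi$ presumes
standard-normal-scale input and raw expression is on an arbitrary scale.
Disable it for pre-normalised inputs. Multi-sample expression is averaged
per region first.

Numerical conventions: $r_i = 0$ where $N_i + M_i = 0$; a region with no
outgoing edges keeps its outflow (exit fraction 0); edge exit probabilities
are clamped to 1 with a warning if $v \Delta t > l_{ij}$; the first atrophy
step uses $r(t-1) = 0$.

## Observed atrophy: W-scores and progression maps

Observed regional atrophy comes from deformation-based morphometry as
age- and sex-adjusted **W-scores**. `fit_normative()` fits, per region, an
ordinary least squares model of control deformation on age, sex and an
intercept; `w_score()` then computes
$(\text{raw} - (\beta_1\,\text{age} + \beta_2\,\text{sex} + \beta_3)) /
\text{SD}_{\text{resid}}$, the residual SD taken over controls with
denominator $n-1$, so the controls' own W-scores have mean 0 and SD exactly
1. Only baseline controls feed the fit (follow-up controls are typically too
few), enforced by filtering. Patient W-scores are averaged per region per
timepoint (`wscore_map()`), and `progression_map()` takes the sign-inverted
follow-up minus baseline difference so that a positive value means atrophy
progression. Because the sign convention of deformation values is
pipeline-dependent, the inversion is a configurable, recorded option rather
than a constant.

## Fitting simulated to observed atrophy

`correlation_curve()` computes the Spearman rank correlation (midranks for
ties) between the simulated atrophy pattern at every timestep and one
observed progression map, and locates the **peak fit** — the maximum
coefficient, earliest step on exact ties (a reproducibility choice). The
quantity correlated is cumulative atrophy $L_i(t)$ by default; per-step
increments are available behind `use = "increment"`. Timesteps with a
constant simulated pattern get a coefficient of 0 with a warning.

Two p-values are reported and labelled: the nominal t-approximation at the
peak ($n-2$ degrees of freedom), and — because the peak is selected over
thousands of timesteps — a search-corrected p from permuting the observed
map's region labels and comparing the true peak with the permuted-peak
distribution. The nominal p overstates evidence; the permutation p is the
honest one for the peak statistic.

## Null models

Four ingredient-randomisations test what the fit depends on:

* **rewired** — Maslov–Sneppen edge swaps preserving the binary degree
  sequence and edge count exactly, weights riding on the swapped edges (the
  weight multiset is preserved exactly); rewired edges take centroid
  distances. Tests dependence on topology.
* **repositioned** — region coordinates permuted, distances recomputed,
  weights untouched. Tests dependence on geometry.
* **gene shuffles** — the synthesis or clearance expression map permuted
  across regions.
* **autocorrelation-preserving surrogates** — `surrogate_expression()`
  generates expression nulls that preserve the value multiset exactly (by
  rank-remapping onto the original values) and the spatial autocorrelation
  approximately, by matching the distance-binned empirical variogram: a
  permutation is smoothed with distance-decay kernels over a grid of
  bandwidths and mixing weights, across several permutation restarts, and
  the candidate whose variogram best matches the original's (count-weighted
  mean relative deviation over 25 bins) is kept. The restart search matters:
  with ~40 regions the per-bin semivariances are noisy enough that a single
  candidate typically sits above a 20% deviation band, while the searched
  surrogate stays within it. The selection metric is deliberately the same
  statistic the test suite asserts on.

`null_peaks()` reruns the full simulation and fit under each draw;
`null_significance()` applies the summary statistic — a one-sample t test of
the null peak distribution against the true peak as the reference constant —
and also reports the nonparametric rank and exceedance proportion of the
true peak among the nulls, since the t test answers a question about the
null *mean* and can reject even when individual null draws approach the true
peak.

A property worth knowing when interpreting repositioned nulls: because they
preserve the entire weighted connection profile, their trajectories visit
nearly the same sequence of atrophy patterns as the original system and
differ mainly in *timing* — which a peak-over-all-timesteps fit forgives by
construction. On data generated by the model itself the repositioned null
mean therefore sits close below the true peak: the t test separates them
cleanly, but individual null draws can come near (or occasionally exceed)
the true peak. Geometry is the weakest lever on this statistic; topology and
the expression maps are much stronger.

## The synthetic-data generator

`synth_spec()` + `make_connectome()` / `make_expression()` / `make_cohort()`
generate self-contained inputs with the statistical structure the pipeline
assumes, so everything is testable without any download:

* a spatially embedded network — regions placed uniformly in a cube (140 mm,
  a brain-scale extent), edge strengths decaying exponentially with distance
  (scale 35 mm) times lognormal noise, thresholded to 35% density, re-linked
  if disconnected; lognormal region sizes;
* spatially autocorrelated expression — Gaussian random fields with
  exponential covariance (length 30 mm), one draw per gene;
* a longitudinal cohort sized to the motivating application — 157 baseline
  controls and 113/104/79 patients at 1-, 2- and 4-year follow-ups, control
  ages ~ N(60.1, 11.9²), patients ~ N(60.9, 10²), 66%/63% male. Controls
  follow a linear age/sex normative model (age slope −0.004/yr, sex offset
  −0.02, per-region intercepts with SD 0.05, residual SD 0.1 — deformation
  values of order 1 with a mild covariate structure); patients additionally
  carry an implanted atrophy signal: the simulated cumulative atrophy
  $L(T^*)$, scaled by a single common factor (the regional SD of the most
  advanced sampled map) and an amplitude of 0.3, subtracted from their
  deformations, with $T^*$ advancing across timepoints (10%, 40%, 60%, 80%
  of the trajectory). The common scale matters: standardising each
  timepoint's map separately would give the mild baseline pattern the same
  weight as the advanced follow-up patterns and erase the progression
  signal the cohort is supposed to carry.

What the generator does **not** emulate: scanner/site effects, registration
error, spatially correlated measurement noise, attrition that depends on
disease severity, streamline-geometry distances (centroid Euclidean
distances stand in), hemispheric organisation, or donor-level transcriptomic
structure. Passing tests on synthetic data therefore demonstrate the
*internal* consistency and statistical machinery of the pipeline, not that
the model fits any particular empirical dataset.

## Problem sizes used by the tests

The suite runs at the scale of the target application (42 regions) but with
trajectories of 2,000–8,000 steps and 100 null repetitions per family
(rather than 10,000 steps and 500 repetitions), sizes chosen so the full
suite completes in minutes while leaving every statistical conclusion
unchanged: the peak fits of interest occur well inside 2,000 steps at the
default parameters, and 100 repetitions give exceedance estimates with a
binomial SE of ~2–5 percentage points. Robustness checks sweep
$\Delta t \in \{0.1,\dots,0.9\}$, $\rho \in \{0.1,\dots,0.9\}$,
$v \in \{0.1,\dots,10\}$ and consensus densities 20–40%, with longer
trajectories (6,000–8,000 steps) for the slow-mobility settings so every
sweep member reaches the fitted stage of the trajectory.

## Known limitations

* Mean-field only: no stochastic per-agent trajectories, hence no
  finite-size fluctuation effects.
* The connectome is static; atrophy does not degrade connectivity over the
  course of a run (no structural plasticity).
* Single seed region; multi-seed inference is out of scope.
* Simulated atrophy is in arbitrary units; only rank-based comparisons with
  observed maps are supported.
* The surrogate expression generator is a compact variogram-matching scheme;
  it preserves binned spatial autocorrelation, not the full covariance
  structure a generative model of the field would.
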