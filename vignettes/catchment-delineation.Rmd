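---
title: "Bayesian catchment-area delineation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian catchment-area delineation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements:
the model and its assumptions, the parameters that matter, how the
synthetic-data generator was calibrated, the numerical choices inside
the sampler and the PSIS-LOO machinery, and what the validation suite
does and does not demonstrate.

## The problem

A hospital's registry is a convenience sample of the surrounding
region. Incidence estimates, temporal trends and risk-factor analyses
computed from it silently assume a population at risk, and that
population lives in the hospital's *catchment area* (CA): the region
the cases actually come from. Classical delineations — a distance
cut-off, or "tracts contributing at least x% of patients" — are
arbitrary. The approach here is model-based: fit a spatial count model
to the registry, and let each tract's posterior say whether it sends
more cases than its population predicts.

## Data preparation

Raw records carry an animal id, species (canine/feline), visit year, a
cancer flag and a census-tract id. Processing follows the registry
conventions of hospital-based veterinary studies:

* **Buffer.** Tracts are restricted to a circular buffer around the
  hospital (233 km — the 145-mile convention — by default); a tract is
  kept when its polygon intersects the circle, or, without polygons,
  when its centroid is within the radius.
* **Deduplication.** One record per animal per calendar year. If any
  record of that animal-year carries a cancer diagnosis, the retained
  record is a cancer record; follow-up visits in the same year are
  dropped. Cancer cases are therefore a subset of visits.
* **Stratification.** Counts are formed on the complete
  tract × species × period grid (explicit zeros), with four five-year
  periods spanning 2000–2019 by default.
* **Populations and offsets.** Tract animal populations are
  `households × 1.6` (dogs) and `× 1.7` (cats). Expected counts use a
  single global rate: `e_ij = (Σy / Σpop) × pop_ij`, the standard
  standardised-incidence-ratio offset, which guarantees `Σe = Σy`.
  The offset sentence that inspired this is ambiguous in the source
  literature; the global-rate reading is the only one that makes `e`
  an expected count, and the `Σe = Σy` invariant makes it testable.

## The hierarchical count model

For tract *i* and stratum *j* (species × period), with offset `e_ij`:

$$Y_{ij} \sim \begin{cases} 0 & \text{w.p. } \pi_{ij} \\
F(\mu_{ij}) & \text{w.p. } 1-\pi_{ij}\end{cases}
\qquad \mu_{ij} = e_{ij}\,R_{ij}$$

$$\log R_{ij} = \beta_0 + \beta_s \,\text{species} + \beta_p\,\text{period} + \nu_i,
\qquad \operatorname{logit} \pi_{ij} = \gamma_0 + \gamma_s + \gamma_p + \eta_i$$

Treatment coding with feline and the first period as references. The
zero component models *structural* zeros — tracts whose owners simply
never use this hospital — distinct from sampling zeros of the count
family. The zero and count components have separate coefficient vectors
and separate tract-effect vectors by default (`share_random_effect`
collapses them); the more general reading, and the one zero-inflated
regression software usually exposes.

Six families are available — Poisson, negative binomial (NB,
mean–dispersion form, variance `μ + μ²/φ`), Conway–Maxwell Poisson
(CMP), and their zero-inflated versions — crossed with two random-effect
priors:

* **exchangeable**: `ν_i ~ N(0, 1/τ)` iid;
* **intrinsic CAR**: `ν_i | ν_{-i} ~ N(mean of neighbours, 1/(m_i τ))`,
  the pairwise-difference density
  `((n−c)/2)·log τ − (τ/2)·Σ_{i∼j}(ν_i−ν_j)²`, improper, handled with a
  per-component sum-to-zero constraint. Isolated tracts (no
  neighbours) revert to `N(0, 1/τ)`, so the CAR prior on an edgeless
  graph *equals* the exchangeable prior — a tested identity.

The CMP family is mean-parameterised: given a target mean, its rate
`λ` is solved by bisection (tolerance `1e-8`) so `μ = e·RR` holds
uniformly across families; its infinite-series normaliser is truncated
when the next term falls below `1e-12` of the running sum.

Priors not pinned down by the source methodology are weakly
informative and configurable: `β ~ N(0, 5²)`, `τ ~ Gamma(1, 0.01)`,
NB shape `φ ~ Gamma(0.01, 0.01)` truncated above `1e-4`, CMP decay
`~ LogNormal(0, 1)`.

## Sampler

`fit_spatial_count()` runs an adaptive Metropolis-within-Gibbs sampler
(4 chains × 4,000 iterations with 25% burn-in by default; the
iteration count is interpreted as the total per chain):

* regression coefficients and the dispersion: per-coordinate random
  walks with Robbins–Monro scale adaptation (target acceptance 0.44,
  warmup only);
* tract effects: *chromatic* single-site updates — the adjacency graph
  is greedily coloured, and all tracts of one colour (mutually
  non-adjacent, hence conditionally independent) are updated in one
  vectorised block;
* precisions `τ`: conjugate Gibbs draws from
  `Gamma(a + df/2, b + q/2)` with the quadratic form `q` over edges
  (CAR) or tracts (exchangeable);
* a **joint rescaling move** `ν → c·ν` with log-normal proposals and
  Jacobian `df·log c`. The (ν, τ) pair forms a funnel: states with
  `ν ≈ 0` and large `τ` are locally sticky, and for the NB families a
  collapsed mode exists in which observation-level overdispersion
  absorbs the spatial signal. Single-site updates alone cross between
  these regions too slowly at desk-scale sample sizes; the collective
  rescaling move traverses the funnel directly. For the same reason the
  tract effects are initialised at jittered empirical log-SIR values
  rather than zero.

Identifiability of the intrinsic CAR follows the common practice of
spatial-epidemiology Gibbs samplers: after each sweep the tract effects
are re-centred within each connected component, and the intercept
re-equilibrates through its own updates.

Convergence is monitored by split-R-hat and effective-sample-size
ratios (Geyer initial-monotone pairing on FFT autocovariances);
`fit_spatial_count()` flags fits whose fixed-effect or precision R-hat
exceeds 1.05, and `diagnostics()` reports the full table (zero-variance
parameters yield `NaN` with a warning). Fixed seeds give bit-identical
draws.

## Model selection

`psis_loo()` estimates the expected log pointwise predictive density
under leave-one-out cross-validation. Importance ratios
`r_s ∝ 1/p(y_i|θ_s)` are tail-smoothed: the largest
`⌈min(0.2 S, 3√S)⌉` ratios are replaced by quantiles of a generalized
Pareto distribution fitted by the profile-posterior/method-of-moments
estimator (with the usual weak-prior regularisation of the shape `k`
towards 0.5), capped at the largest raw ratio. `loo_compare()` ranks
models and reports pairwise ELPD differences with standard errors from
the pointwise differences. Two numerical notes: when all draws are
identical the smoothing is undefined and `elpd_i` degenerates exactly
to the pointwise log-likelihood (`k = NaN`); and because the tail size
adapts to the draw count, duplicating every draw reproduces the ELPD
only to ~0.1%, not bit-exactly.

## Delineation

`exceedance()` uses the count-component tract effect: `q_i` is the
fraction of posterior draws with `ν_i > 0`, equivalently `RR_i > 1`.
The zero component describes structural absence of reporting, not case
intensity, so it does not enter the default exceedance (both the zero
effect and the sum are available by argument). Membership is
`q_i ≥ threshold` — a closed comparison, reading the threshold as the
minimum qualifying value — and is provably nested across thresholds.
The primary area is the member component (under the tract adjacency
restricted to members) containing the hospital's tract; if the hospital
tract is not a member, the largest component wins, ties broken by
proximity. Per-period catchments refit the model on each period's
subset separately (species stays a fixed effect), keeping period
estimates independent; the combined CA is their intersection. Reported
percentages are rounded half-up to one decimal, full precision kept
alongside.

## Determinants

Tract membership is regressed on distance to hospital and average
household income (scaled to $1,000s), both centred; by default both are
also scaled by their SD, because per-SD odds ratios are the
interpretable unit at this scale — a per-km distance OR is numerically
indistinguishable from zero or one. The centring/scaling constants are
recorded so either convention can be reproduced. Models are fitted by
IRLS (`glm`, tolerance `1e-8`), with (quasi-)separation detected and
raised as an error; terms enter in the order distance, income,
interaction, and the sequential (type-I) deviance drop of each term is
reported. ROC curves use every distinct score; AUC is the rank
(Mann–Whitney) statistic with half-credit for ties, which equals the
exhaustive pairwise comparison — a tested identity. Group income
contrasts use one-way ANOVA (for two groups, `F = t²`).

## The synthetic generator and its calibration

`make_scenario()` draws a complete study with known truth:

* a 20 × 20 grid of 3-km square tracts near the hospital (queen
  adjacency), households uniform in 400–2,500, income declining with
  distance ($300/km from a $90,000 base, SD $12,000, floored at
  $10,000);
* tract effects `ν` (count) and `η` (zero) sampled *exactly* from the
  intrinsic CAR distribution by eigendecomposition of the graph
  Laplacian: eigenvector coefficients `N(0, 1/(τλ_k))` on the positive
  spectrum, null space set to zero — which *is* the sum-to-zero
  constraint;
* counts from the ZINB model (species effect `log 3`, period drift
  0.02/0.1/0.3, structural-zero share ≈ 25%, NB dispersion 5), offsets
  `e = 8×10⁻⁴ × population`, giving visit totals of order 10⁴; cancer
  cases are binomial thinnings of visits (rate 0.118), so
  `cancer ≤ visits` by construction;
* the true catchment is defined as `{i : ν_i > 0}`, which makes
  delineation recovery a crisp binary classification problem.

Two generator constants deserve justification. The CAR precision
default `τ = 0.25` gives a marginal tract-effect SD around 1.1 on the
default grid, i.e. tract-level attendance rates spanning roughly a
factor of ten — the kind of contrast a real catchment exhibits between
tracts adjacent to the hospital and tracts a hundred kilometres out.
The NB dispersion default 5 encodes *mild* residual overdispersion:
once species, period and tract structure are modelled, registry counts
are not far from Poisson, and variance three times the mean (as a
dispersion near 1 would imply at these means) would be unrealistic. At
registry scale (hundreds of thousands of records) much smaller spatial
effects are detectable; a desk-scale scenario must carry proportionally
larger effects for the same questions to be answerable at all.

What the generator does **not** emulate: the spatial field is drawn
independently of distance and income, so membership in the synthetic
catchment is, by construction, unrelated to the determinant covariates,
and the synthetic "primary" block is small because member patches
scatter over the grid instead of ringing the hospital. Passing recovery
tests on this scenario therefore demonstrates that the model recovers
what it simulates — not that distance or income effects are estimable
from observational registries; determinant recovery is validated on a
separate scenario whose membership follows a known logistic law in
distance and income with a negative interaction. Real census
geographies (irregular polygons, islands, highly unequal tract
populations) and road-network travel times are likewise out of the
generator's scope; user-supplied distance columns let true driving
distances replace great-circle ones.

## Problem sizes in the validation suite

The test suite and the acceptance script size their runs for a single
CPU: small fits use 6–8×8 grids with 2 chains of a few hundred
iterations; the reference recovery runs use the full 20 × 20 scenario
with 4 chains × 1,000 iterations (25% burn-in), which recovers the
spatial field at Pearson r ≈ 0.9 and delineates at ≈ 0.65 sensitivity /
1.0 specificity against the simulated truth. The PSIS-LOO oracle uses a
conjugate Gamma–Poisson model whose leave-one-out refits are available
in closed form (negative-binomial posterior predictives), so "exact
LOO" needs no numerical refitting.

## Known limitations

* The intrinsic CAR re-centring gauge is the field-standard
  approximation, not an exact constrained sampler; its perturbation is
  absorbed by the intercept within a sweep.
* ZINB mixtures are weakly identified when counts are small and
  zero-inflation is mild; the sampler's rescaling move mitigates but
  cannot remove genuine posterior ridges between dispersion and
  spatial variance.
* CMP fits are practical only for small data: every likelihood
  evaluation solves a bisection per observation on a truncated series.
* Queen/rook adjacency from polygons assumes shared boundary points
  are vertices of at least one polygon (true of census tilings);
  arbitrary overlapping geometries are not handled.
* Exceedance uses the tract random effect alone, not the full stratum
  relative risk; with covariate-dependent alternatives the catchment
  would vary by species and period.
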