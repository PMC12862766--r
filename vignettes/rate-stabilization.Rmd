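---
title: "Rate stabilization with CAR models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate stabilization with CAR models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Health surveillance increasingly asks for rates at the census-tract
level, where populations of a few hundred to a few thousand make crude
rates `Y/n` so noisy that most cells fail display rules (for example the
"fewer than 16 events" convention for unsmoothed death rates) and end up
suppressed. Small area estimation addresses this by borrowing strength
across neighboring units: a tract's rate is informed by its own counts
*and* by its neighbors', so small-population tracts get stabler, more
precise estimates.

`ratestab` implements the Besag-York-Mollié (BYM) family of conditional
autoregressive (CAR) models for this purpose, together with the full
estimate-quality layer needed to publish the results responsibly:
credible intervals, relative precision, levels of reliability,
suppression flags, direct age-standardization, aggregation across
domains, comparison against a reference rate, and exceedance
probabilities.

## Models

All three samplers share the cell-level likelihood

* binomial (default): `Y ~ Binomial(n, theta)` with
  `logit(theta) = beta + Z + eps`, or
* Poisson: `Y ~ Poisson(n * theta)` with `log(theta) = beta + Z + eps`,

where `beta` is an intercept per group/period slice, `Z` a spatially
structured random effect, and `eps` iid heterogeneity. The binomial
default keeps `theta` in (0, 1) and is appropriate when the counts are a
census of the population at risk; the links are the canonical choices
for each family.

**UCAR** (`fit_ucar`): one count per region. `Z` carries the intrinsic
pairwise-difference CAR prior on the adjacency graph,
`p(Z | tau2) ∝ exp(-1/(2 tau2) * sum over edges (Z_i - Z_j)^2)`, the
classic two-effect BYM form.

**MCAR** (`fit_mcar`): region-by-group counts. The group vectors `Z_i`
follow the proper multivariate CAR of Gelfand and Vounatsou:
conditionally `Z_i | Z_(-i) ~ N(rho * mean of neighbors, Sigma / m_i)`
with `m_i` the neighbor count, between-group covariance `Sigma` under an
inverse-Wishart prior, and spatial propriety parameter `rho` given a
uniform prior over a discrete grid (log-determinants precomputed from
the eigenvalues of the degree-normalized adjacency).

**MSTCAR** (`fit_mstcar`): region-by-group-by-period counts, periods
equally spaced. The group-vector fields evolve as a first-order
autoregression, `Z_t = A Z_(t-1) + innovation`, with `A = diag(ar_g)`
(one autocorrelation per group, each on a discrete uniform grid) and
multivariate-CAR innovations. The first period carries the
innovation-scale MCAR prior. Two consequences we rely on in testing: a
single-period MSTCAR is *exactly* an MCAR, and a single-group MCAR
approximates the UCAR (proper CAR at `rho = 0.99` versus the intrinsic
CAR — close, but genuinely different priors, so agreement is judged
relative to posterior spread, not to machine precision).

A scalar-per-group AR was chosen over a full temporal covariance because
it keeps the temporal dependence interpretable and the conditional
updates closed-form; the per-group grid update is exact given the rest
of the state.

## Sampler design

Metropolis-within-Gibbs, in a fixed sweep order (imputation, structured
effects by period and coloring block, re-centering, heterogeneity,
intercepts, variances, `Sigma`, `rho`, `ar`). Design points:

* **Coloring blocks.** Non-adjacent regions have conditionally
  independent full conditionals, so the sweep updates whole color
  classes of a greedy graph coloring at once with vectorized
  Metropolis steps. This is an exact Gibbs blocking, not an
  approximation; it is what makes a pure-R sampler fast enough
  (thousands of sweeps per minute on a 100-region lattice).
* **Adaptation.** Random-walk scales adapt per cell toward acceptance
  0.43 by a Robbins-Monro recursion during burn-in only and are frozen
  afterwards, preserving detailed balance for every retained draw.
  Post-burn-in acceptance fractions are reported per block and in
  practice land in [0.2, 0.6].
* **Identifiability.** The intercept is kept and `Z` is re-centered to
  sum to zero within each group-period slice after every sweep, with
  the removed mean absorbed into the intercept so cell rates are
  untouched.
* **Conjugate updates.** `tau2` and `sigma2` are inverse-gamma Gibbs
  draws (the intrinsic CAR contributes rank `N - #components`); `Sigma`
  is an inverse-Wishart draw; `rho` and `ar_g` are sampled exactly on
  their grids from categorical full conditionals.
* **Censored counts.** Privacy-censored cells (count known only to lie
  in `[0, censor_bound - 1]`) are re-imputed every sweep by inverse-CDF
  sampling of the likelihood truncated to that range; imputed draws are
  saved alongside the rate draws.
* **Determinism.** One seeded RNG drives the whole sweep in a fixed
  stream order (imputation, then effect blocks in coloring order, then
  heterogeneity, intercepts, variances, grids), so a fixed
  (seed, input, config) reproduces draws bit-exactly, and identical
  fits persist to byte-identical files.
* **Degenerate inputs.** Zero-population cells contribute nothing to
  the likelihood; their rates are driven by the prior and neighbors and
  are reported with a log message. A binomial fit refuses `Y > n`. A
  non-finite initial log-posterior is an immediate diagnostic error.

Default priors are standard weakly-informative disease-mapping choices:
`beta ~ N(0, 10^2)`, `tau2, sigma2 ~ InvGamma(0.5, 0.005)`,
`Sigma ~ InvWishart(G + 1, I)`, `rho` uniform on
`{0, 0.05, ..., 0.95, 0.99}`, `ar_g` uniform on `{0, 0.05, ..., 0.95}`.
Chain defaults are 6,000 sweeps with 2,000 burn-in and no thinning.
All are overridable through `model_config()`. Initialization: intercepts
at the empirical link-scale pooled rate, effects at zero, variances at
one, censored counts at half their bound.

## The estimate-quality layer

Estimates are posterior medians; intervals are type-7
(linear-interpolation) sample quantiles at `(1 - a)/2` and `(1 + a)/2`.
Relative precision is the median divided by the interval width, and an
estimate is "reliable" only when that ratio strictly exceeds 1 — a ratio
of exactly 1 fails. The level of reliability is the largest level on a
grid (`{0.50, 0.55, ..., 0.95, 0.99}` by default) at which the estimate
is still reliable; it is well defined because interval width is
non-decreasing in the level. Constant draw sets get relative precision
`+Inf` (a degenerate posterior is maximally precise) and the top grid
level.

Suppression is always a flag, never a deletion: model-based tables are
flagged when unreliable at the table's level or when the population
falls below a threshold (default 100; 30 is the other common choice),
crude tables when the event count falls below a minimum such as 16.
Users can re-threshold without refitting.

Age-standardization and group aggregation are applied draw-wise —
`theta_std = sum_g w_g * theta_g` per draw for fixed standard weights,
`sum_g n_g * theta_g / sum_g n_g` for population-weighted merges — so
credible intervals downstream reflect the transformation. Draw-wise
application (rather than standardizing the point estimates) was chosen
deliberately: medians are computed last. Weights for the 2000 and 2010
US Standard Populations in ten-year bands ship as in-code constants
(renormalized over the bands present in an analysis); any custom
standard can be supplied as a `group`/`weight` table.

Comparison to a reference rate classifies each cell by whether its
credible interval excludes the reference; unreliable estimates can
still be significantly different. Exceedance probabilities count draws
strictly above the reference, so `P(> v) + P(<= v) = 1` exactly and
ties do not exceed.

## Adjacency

Neighbor lists follow the usual polygon-contiguity semantics:
symmetric, irreflexive, and every unit must have at least one neighbor
(the CAR prior is undefined for isolated units — the package refuses
them by default rather than silently dropping them). Queen contiguity
(any shared boundary point) is the default, matching common
census-tract practice; rook requires a shared edge. Contiguity is
computed from GeoJSON polygon layers by exact vertex comparison with no
snap tolerance — layers digitized with coincident border vertices (the
norm for census products) work directly; layers with sliver gaps should
be pre-cleaned or supplied as a GAL file. GAL records are keyed by the
unit IDs themselves so files join unambiguously against event and
population tables.

## What the synthetic worlds do and do not show

`simulate_dataset()` draws from the model's own generative assumptions:
intrinsic-CAR fields via the spectral decomposition of the graph
Laplacian (exact under the sum-to-zero constraint), proper-MCAR fields
via the Cholesky factor of `D - rho W`, AR(1) propagation across
periods, uniform populations, and counts from the likelihood. The
default scenario is a miniature of a sparse tract-level mortality
setting: a 10 x 10 lattice (a state's tract map in miniature),
populations 50-2,000, baseline rate 0.012 (about 1,200 per 100,000),
`tau2 = 0.2`, `sigma2 = 0.05` — sparse enough that a 16-event crude
rule suppresses well over 30% of cells, so the smoothed-versus-crude
suppression contrast is exercised, and the qualitative pattern of a
real tract-level analysis (most suppression removed by smoothing,
further reduced at a relaxed 90% level) reproduces.

Because the generator and the model share assumptions, passing tests
demonstrate *internal* correctness — nominal interval coverage (the
package checks 95% coverage lands in [90%, 98%] over 100 cells), lower
RMSE than crude rates, parameter-sign recovery — not robustness to real
data's irregular geographies, non-uniform populations, model
misspecification, or reporting artifacts. Test problem sizes are chosen
as the smallest that make the statistical checks sharp: 10 x 10
lattices for recovery and suppression contrasts, a 50 x 50 lattice for
the law-of-large-numbers generator check, 12,000-sweep chains for the
nesting comparison, 20,000+ draws for the conjugate-oracle and
truncated-imputation goodness-of-fit checks.

Two identifiability facts surfaced by the synthetic studies are worth
knowing: the between-group covariance of the latent fields is weakly
identified when populations are small (its posterior correlation can
sit near zero even when the true correlation is 0.8 — the
inverse-Wishart prior centers correlations at zero and sparse counts
carry little information about cross-group covariance), and `rho` is
only loosely determined on small lattices. Neither affects the rate
estimates materially, which is what the tools exist to produce.

## Known limitations

* Inputs are assumed to be a census of the population at risk; survey
  weights and undercount adjustment are out of scope.
* The proper-CAR multivariate models can produce relative precisions
  above 1 for cells with zero observed events (over-precise smoothing);
  this is exactly why `apply_suppression()` supports a population
  threshold in addition to the reliability rule.
* Restricted-smoothing CAR variants that bound the strength of spatial
  smoothing are not implemented; the `restricted` flag errors with a
  pointer to that literature.
* Comparison is against a single reference value; pairwise
  region-versus-region interval-overlap matrices and multiplicity
  adjustment across regions are out of scope.
* Boundary input is GeoJSON or GAL; other GIS formats should be
  converted upstream or expressed as a GAL neighbor list.
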