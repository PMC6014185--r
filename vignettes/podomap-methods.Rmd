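---
title: "Mapping podoconiosis: suitability ensembles, geostatistical prevalence and burden arithmetic"
author: "podomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping podoconiosis: suitability ensembles, geostatistical prevalence and burden arithmetic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Podoconiosis is a non-filarial lymphoedema caused by long-term barefoot
exposure to irritant volcanic clay soils. Its burden in an endemic country is
estimated from two ingredients that are never available in the same place:
community screening surveys (number screened, number of confirmed cases, a
coordinate) and country-wide gridded environmental covariates (soil silt and
clay fractions, soil pH, elevation and slope, precipitation, land-surface
temperature, vegetation, distance to water bodies, night-light distance).
`podomap` implements the two-stage analysis pipeline used for this kind of
mapping, end to end, on a single aligned planar-km raster grid:

1. **Environmental limits.** An ensemble of boosted regression trees (BRT)
   and random forests (RF) is trained on presence/absence/background labels
   to score *environmental suitability*, which is thresholded into a binary
   limits map: the region where transmission is environmentally possible.
2. **Prevalence and burden.** Inside those limits, a binomial logistic
   geostatistical model with a spatially correlated random effect predicts
   prevalence with uncertainty; multiplying by an adult population surface
   and aggregating over administrative polygons yields population at risk
   and case counts with 95% bounds, plus exceedance maps against the 1%
   endemicity policy threshold.

Because no survey microdata are distributed with the package, a synthetic
world generator is a first-class module: every stage is exercised and tested
against data whose truth is known exactly.

## Stage 1: the suitability ensemble

Communities are labelled endemic (1) when at least one confirmed case was
recorded, else non-endemic (0). Three data issues are handled before
modelling:

* **Geographic sampling imbalance.** One region is typically screened
  exhaustively while the rest of the country is sparsely sampled. A random
  75% subset of the positive communities in the over-sampled region is
  retained (`subsample_positives()`, fraction configurable).
* **Pseudo-absences with matched bias.** 500 background points (the
  module default) are sampled at cell centres with probability proportional
  to a *sampling bias surface*: per-cell occurrence counts smoothed by an
  isotropic Gaussian kernel (`build_bias_surface()`). The bandwidth defaults
  to Silverman's rule on the presence coordinates; it is the single most
  influential free parameter of this stage and is exposed in the config.
  Background points may coincide with presence cells; they are not excluded
  (no exclusion is standard, and an optional flag can be layered on by
  filtering the sampled points).
* **Weight balance.** Presences get weight 1; observed absences and
  background points share the common weight
  `n_presence / (n_absence + n_background)`, so both sides of the
  classification problem carry equal total weight (`assign_weights()`).

`run_ensemble()` repeats, 100 times by default: draw a random 80% training
split, fit BRT (learning rate 0.005, interaction depth 4, tree count chosen
by early stopping on an internal 10% fold, capped at 5000) and RF (500
trees, sqrt(p) candidate features), evaluate on the held-out 20% (AUC by the
tie-corrected rank formulation, TSS and PCC at the Youden-optimal test
threshold), and predict the full grid. Runs with AUC < 0.8 or TSS < 0.7 are
disregarded; the ensemble surface is the per-cell mean of the survivors with
empirical 2.5/97.5 percentile bounds. "Up to four interactions" is read as
tree depth 4; BRT regularisation terms that would break weight-scale
invariance are disabled, so doubling all weights changes nothing.

The binary cut-off maximizes the unweighted mean of sensitivity,
specificity and PCC over all distinct-score midpoints (ties resolved to the
lower threshold); Youden's J is a config alternative. BRT and RF runs are
pooled into one ensemble after selection — a per-algorithm split is a
one-line filter on the run table.

## Stage 2: the geostatistical prevalence model

For community $i$ with $n_i$ screened and $y_i$ cases at location $x_i$,

$$y_i \sim \mathrm{Binomial}(n_i, p_i), \qquad
  \operatorname{logit} p_i = d(x_i)^\top \beta + S(x_i) + Z_i,$$

where $S$ is a zero-mean Gaussian process with exponential covariance
$\sigma^2 \exp(-\|a-b\|/\phi)$ (Matérn with smoothness 1/2; the smoothness
is a config choice, exponential being the package default) and
$Z_i \sim N(0, \tau^2)$ is an unstructured community-level nugget. The
nugget absorbs within-community and sub-kilometre variation; it is
*excluded* from predicted prevalence surfaces, which target $S$ only —
standard model-based-geostatistics practice.

**Inference.** `geostat_fit()` maximizes the Laplace approximation of the
marginal likelihood: a joint Newton solve over $(\beta, U)$ (with
step-halving) nested inside a Nelder-Mead search over
$(\log\sigma^2, \log\phi, \log\tau^2)$, started from a weighted
least-squares exponential-variogram fit of empirical-logit residuals of a
non-spatial binomial GLM, with two additional dispersed starts. A
Monte-Carlo refinement (`method = "mcml"`) re-maximizes an importance-
sampling likelihood whose proposal is the Laplace approximation at the
pilot estimate, with common random numbers so the objective is smooth. The
Laplace objective is the default: at the per-community sample sizes the
package simulates, its error on the log-likelihood is below 0.01 (verified
in the tests against exact 2-D quadrature at two communities), and its
estimates agree with an independent Laplace engine (glmmTMB with an
exponential spatial covariance) to two decimals on all four parameters.
Standard errors come from the joint-mode Hessian ($\beta$) and a numeric
Hessian of the profile likelihood (covariance parameters, delta method).

**Prediction.** `geostat_predict()` draws $(\beta, U)$ jointly from the
Gaussian approximation at the mode, conditions $S$ at every unmasked cell
inside the limits map on the drawn $U$ (exact conditional covariance with
a Cholesky factor; grids are kept at a few thousand cells so the dense
algebra is exact), and transforms to prevalence. Mean, percentile bounds,
per-cell predictive SD and exceedance probabilities are empirical over the
(default 1000, minimum 100) samples; the sample matrix is retained so
exceedance can be recomputed at any threshold without re-sampling.

**Validation.** `variogram_validation()` compares the empirical
semivariogram of standardized empirical-logit residuals against an envelope
built from datasets simulated under the fitted model at the same locations.
The envelope is *simultaneous*: the per-bin quantile level is widened until
97.5% of the simulated curves lie fully inside their own band, so the band
is a conservative global 95% envelope. A pointwise 95% band would reject
model-consistent data in a large fraction of runs once a dozen bins are
compared jointly; with the global band, data simulated from the fitted
model itself passes in well over 90% of replicates while a strong
unmodelled spatial trend is still rejected.

## Burden arithmetic

`adult_population()` scales a gridded population surface by the adult (15+)
fraction (scalar or raster; default 0.55 in the synthetic pipeline, a
typical sub-Saharan adult share). `cases_surface()` multiplies the
prevalence mean and bounds cell-wise by the adult surface — grids must
align bit-exactly; the package never resamples silently. Population at risk
counts adults in cells where the binary limits map is 1.
`aggregate_burden()` assigns each cell to the polygon containing its centre
(even-odd ray casting; overlapping polygons are an error listing the
offenders) with a residual "unassigned" row so unit sums conserve grid
totals exactly. `summarize_endemicity()` reports threshold counts and
shares; shares are computed on column sums rather than any printed grand
total, which makes them robust to presentation rounding in published
tables.

## The synthetic world

`synth_config()` defines a self-contained "mini-Cameroon" on a planar km
grid (default 60 x 60 km of 1 km cells):

* **Covariates**: independent stationary Gaussian fields with exponential
  correlation at stated ranges (default 15 km), simulated *exactly* by
  Cholesky factorisation of the correlation matrix and standardized. Exact
  simulation is what makes parameter-recovery tests meaningful; it caps the
  grid at 10,000 cells, which is enforced with a clear error.
* **Truth**: logit-linear prevalence in the covariates plus a spatial GP
  (default $\sigma^2 = 1$, $\phi = 10$ km) — the same family the
  geostatistical stage estimates. True suitability is the indicator
  `prevalence > 0.01`, aligned with the endemicity threshold.
* **Surveys**: 748 communities at distinct cell centres, 90% inside an
  over-sampled quadrant (emulating the 672-of-748 regional screening
  campaign of the motivating study design), 50-500 screened each (mean
  ~275, matching the observed mean of ~273), with cases drawn binomially at
  `invlogit(logit(p) + z)`, `z ~ N(0, tau2)` — the community nugget applied
  on the logit scale to match the model family being recovered.

Two named scenarios fix the study conditions used in the automated checks:

* `strong_signal_config()` — covariate slopes large relative to the
  residual spatial process (standardized-slope magnitudes 8/5/5 against
  $\sigma^2 = 0.25$, $\tau^2 = 0.05$), ~20% of the landscape suitable, and
  200-500 screened per community. In this regime presence labels are
  essentially environmentally determined, and held-out AUC/TSS land in the
  low-0.9s/high-0.7s — the regime in which suitability ensembles are
  reported to discriminate in practice. This scenario also backs the
  bundled pipeline world.
* The **recovery scenario** for the geostatistical stage keeps the
  covariance truth ($\sigma^2 = 1$, $\phi = 10$ km, $\tau^2 = 0.25$, 300
  communities on a 50 km domain) but uses an informative screening design:
  5% baseline prevalence with 200-600 screened, i.e. roughly 10-30 expected
  cases per community. The nugget is identifiable only when per-community
  binomial noise on the logit scale (about $1/(n p (1-p))$) is below
  $\tau^2$; at 0.4% prevalence with a few hundred screened the nugget
  cannot be pinned to a factor of 2 by *any* estimator (we verified the
  likelihood at the estimate exceeds the likelihood at the truth, and that
  an independent engine returns the same estimates). This is a design
  choice about what the recovery study can demonstrate, stated here once.

What passing the synthetic checks does **not** show about real data: the
generator draws covariates independently (real soil/climate/topography
covariates are strongly collinear), has no measurement error in
coordinates, no missing-data structure beyond a nodata mask, no sensor
artefacts, and its communities sit exactly at cell centres. Results on real
surveys inherit none of these simplifications.

## Numerical choices and degenerate inputs

* Cell containment is half-open: points on shared edges belong to the cell
  right/below, so extraction and nearest-neighbour ties are deterministic.
* Distance and slope refuse degree-unit CRS labels; the pipeline is
  planar-km only. Slope uses Horn's 3 x 3 kernel with index clamping at
  borders (one-sided differences).
* A tiny (1e-10) diagonal jitter keeps correlation matrices positive
  definite; the GP conditional covariance gets 1e-8 before factorisation.
* `sigma2` estimates below 1e-3 trigger a "no spatial signal" warning;
  single-class training sets, empty ensembles, degenerate bias densities,
  misaligned grids and overlapping polygons are all hard errors with
  actionable messages.
* All randomness flows from one master seed through `derive_seed()`, a
  31-bit multiplicative string hash, so every stage is independently
  rerunnable and the pipeline manifest is hash-stable.

## Problem sizes

The shipped tests and the acceptance script run on grids of 225-3600 cells,
120-748 communities, ensembles of 4-16 runs, 300-2000 posterior samples,
and recovery/validation studies of 10-20 seeds; these sizes make every
Cholesky factorisation exact while keeping a full run in minutes on one
core. Country-scale grids need low-rank approximations that are explicitly
out of scope.

## Known limitations

* The likelihood is approximated (Laplace; optional importance-sampling
  refinement). For very small per-community counts variance components are
  weakly identified — a property of the data, not the approximation.
* Exceedance and CI surfaces are empirical over a finite sample matrix;
  with 1000 samples, probabilities below ~0.002 are quantized.
* Background sampling at cell centres (not continuous locations) keeps
  feature extraction exact but ties background resolution to the grid.
* The CLI wrapper (`inst/cli/podomap.R`) is a thin layer over
  `run_pipeline()`; the R functions are the primary interface.
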