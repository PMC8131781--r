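---
title: "Modelling non-equilibrium invaders: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling non-equilibrium invaders: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invaniche)
```

## The problem

A species invading a new region is usually not at equilibrium with its
environment: climatically suitable places exist that it simply has not
reached yet. A presence-background niche model calibrated only on the
invaded range then treats those unreached sites as evidence of absence and
learns a niche that is too narrow — it transfers poorly and understates the
final extent of the invasion. `invaniche` implements a workflow built
around this problem: reciprocal maximum-entropy climate models for the
native and invaded ranges, a background-weighting scheme that uses the
native model to discount likely "false absences" in the invaded range, and
a regional layer of distribution and severe-impact models that separate
where an invader *occurs* from where it does *damage*. Because the real
inputs of such studies (occurrence archives, gridded climate, forestry
maps) are external data products, the package ships a virtual-species
simulator that generates landscapes and occurrence data with known
generative truth, so every step of the chain can be validated against an
oracle.

## The maximum-entropy model

The core estimator is the presence-background MaxEnt model in its penalized
Gibbs formulation. Covariates are standardized by their background mean and
sd and expanded into linear and quadratic features `z`, `z^2` (one-hot
indicators for categoricals); no hinge or threshold features are offered —
the workflow deliberately restricts itself to smooth quadratic response
curves. With features `f(x)`, background base weights `w(x)` and
coefficients `lambda`, the model density over the background sample is

    q(x) = w(x) exp(lambda . f(x)) / Z,
    Z = sum_b w(b) exp(lambda . f(b)),

and fitting minimizes the average presence negative log-density plus an L1
penalty `sum_j rho_j |lambda_j|` with `rho_j = beta * s_j / sqrt(m)` (`s_j`
the feature sd over the background, `m` the presence count). The default
`beta = 3` is a deliberately conservative setting appropriate for modest
sample sizes and broad extents; the `beta` path is monotone (larger `beta`
never increases the L1 norm) and is exercised in the tests over
`{0.5, 1, 3, 10}`.

The solver is FISTA (accelerated proximal gradient) with backtracking line
search and adaptive restart, run to a relative objective tolerance of 1e-8
with a 5,000-iteration cap. The problem is convex, so the tests audit the
returned optimum against random perturbations and against an independent
derivative-free optimizer on tiny instances. One genuine failure mode is
worth knowing: if the presence feature mean lies outside the background
feature hull by more than the penalty margin (possible with very small
samples and small `beta`), the objective is unbounded and coefficients grow
without limit; `maxentFit()` warns when coefficients exceed 50, which in a
standardized feature space only happens in that regime.

Predictions use the cloglog transform by default
(`1 - exp(-exp(H) * raw)`, with `H` the entropy of the fitted density over
the training background), matching modern MaxEnt convention; logistic and
raw outputs are available. Covariates are clamped to their training range
before expansion, so projections beyond the calibration domain flatten
rather than extrapolate the quadratic — this matters for the reciprocal
native/invaded projections, and it is also why the background-weighted
model should be inspected before trusting it far outside the occupied
climate space (see Limitations).

## Background weighting for non-equilibrium invaders

The weighted model keeps the invaded-range presences but attaches a weight

    w(p) = 1 / (1 + (p / (1 - p))^2)

to each invaded background point, where `p` is the *native* model's
suitability at that point (`w(1) = 0` by continuity). Background points the
native model considers unsuitable keep weight ~1 — they probably are true
absences — while suitable-but-unoccupied points are discounted, so the
invaded model is no longer punished for predicting presence where the
invader has merely not arrived. The weights enter as the base measure of
the partition function only; presence terms are never weighted, and an
all-ones weight vector reproduces the unweighted fit bit for bit. No
rescaling of weights is applied: the dual is invariant under positive
scaling of the base measure, which the tests verify indirectly through the
all-ones identity.

## Evaluation: AUC and the continuous Boyce index

AUC is the Mann-Whitney probability that a random presence outscores a
random background point (ties count one half), computed from ranks and
therefore identical to exact pair counting. The continuous Boyce index
slides 101 overlapping windows across the score range, forms the
presence-to-expected ratio `P/E` per window, collapses consecutive
duplicated ratios, and reports the Spearman correlation between window
position and `P/E`. The window width default is 2% of the score range.
This width was chosen on statistical grounds: the index's null
distribution (presences drawn at random from the landscape scores) should
concentrate near zero, and that requires enough effectively independent
windows — at the traditional 10% width there are only about ten, and the
null index is spread over much of [-1, 1]; at 2% (~50 independent windows)
the null concentrates inside (-0.3, 0.3) in over 90% of simulated runs.
Both window parameters are recorded in every evaluation report and can be
changed per call. A constant prediction is reported as degenerate (AUC 0.5,
CBI `NA`) rather than an error.

## The virtual-species generator

The simulator produces what the analysis chain assumes about real data,
and nothing more:

* **Climate** — `K` standardized Gaussian random fields (white noise
  convolved with a Gaussian kernel, wrap-around at the grid edge) that are
  empirically whitened and remixed so their sample correlation matrix
  equals a requested target exactly; spatial autocorrelation range and
  collinearity structure are the two knobs that matter for screening and
  for front-truncation experiments.
* **Habitat, host, elevation** — habitat classes are the argmax of
  independent smoothed fields (clustered patches), host presence is a
  smoothed field thresholded at the requested prevalence, and the DEM is a
  smooth nonnegative surface.
* **Species truth** — a logistic-quadratic niche over the climate layers
  (`a2 <= 0`, so always unimodal), an optional host dependence, a yearly
  dispersal radius, and three ordered cutpoints that map true suitability
  plus a small uniform jitter (±0.05) to a 4-level severity score, so
  severity tracks climate without being deterministic.
* **Sampling** — equilibrium sampling draws cells with probability
  proportional to suitability (times host), one record per cell-year;
  invasion-front sampling starts at introduction points and each year
  colonises cells within the dispersal radius of the occupied set, again
  proportionally to suitability. The occupied set is monotone and every
  new record is within the dispersal radius of an earlier one.

Grids default to 0.5 km cells. The real studies this emulates work at
about 1 km pixels, but a sub-km synthetic grid keeps the per-km²
patch-fragmentation and heterogeneity metrics non-degenerate while all
layers still share a single grid.

What the generator does *not* emulate: real marginal distributions of
bioclimatic variables, anisotropic spatial structure, observation bias,
geodesic geometry (all distances are planar Euclidean kilometres), or any
actual geography. Tests passing on this generator show the chain is
correct and that the weighting mechanism behaves as designed under niche
truncation; they do not show that any particular real invasion satisfies
the generator's assumptions.

## The reference experiments

Two seeded experiment builders define the package's study conditions.

**Two-region truncated-niche scenario** (`twoRegionScenario()`): one truth
with its optimum placed in the upper availability tail of the first
climate variable (optimum at `clim1 = 2` against availability ~N(0,1); on
the logit scale `-10 + 12 z - 3 z^2`), so that only a minority of either
region is suitable and calibration discrimination is high. The native
region is sampled at equilibrium (400 records). The invaded region has the
same truth but its `clim1` availability shifted down by 0.8 sd, with the
introduction placed on the lower flank of the niche and five years of
dispersal-limited spread (8 km/yr, 70 records/yr): the front occupies a
truncated slice of the niche while fully suitable patches remain unreached
— exactly the regime background weighting addresses. An earlier, centred
parametrization of this scenario produced weak calibration and no
truncation and was replaced by this design; the displaced optimum is what
creates both a crisp niche and something for the weighting to recover.

**Regional invasion scenario** (`regionalScenario()`): one 160×160 half-km
landscape, a host-dependent species, six invasion years; the last year's
records are the calibration presences and the earlier years define the
dispersal-distance covariates. The regional models take the *true*
suitability raster as their climate-suitability covariate, which
conditions the distribution-vs-severity question on an exact climate layer
instead of compounding it with climate-model estimation error (the
estimated chain is exercised separately by the two-region experiment and
the end-to-end pipeline test).

Problem sizes used by the test suite and acceptance script — 10,000
background points and 10 replicate 70/30 splits for the climate models;
4,000 background, 5 replicates and 5 permutations per variable for the
ten-seed regional experiments — are the package's chosen testing
conditions; they keep the full suite under a couple of minutes while
leaving all qualitative orderings stable across seeds.

## Regional covariates

`buildRegionalCovariates()` assembles the standard landscape covariate
stack: climate suitability rescaled to percent, elevation, aspect
categories (down-slope facing direction binned into N/E/S/W with a flat
code that one-hot-expands to all zeros), forest cover and mean basal area
within 1 km, per-km² patch fragmentation (`P/C`) and heterogeneity
(`P*C`), host cover within 10 km (a yearly flight distance), and the
minimum distance to the previous year's records — all records for the
distribution model, high-severity (levels 3-4) records for the severity
model. Focal windows are circular on cell centres and shrink at the grid
border (no padding), which keeps border means unbiased. Patch connectivity
defaults to 4-neighbour (8 available); blocks are anchored at the raster
origin and partial edge blocks use their available cells. Basal area on a
synthetic landscape has no inventory source, so a deterministic stand
proxy (35 m²/ha on forest cells, declining with elevation) stands in; any
real basal-area raster can be passed instead. The "Reduced" model pair
refits with background restricted to 10 km buffers around the presences
and masked to host cells, dropping the distance and host-cover covariates
— the design that asks what limits the species beyond dispersal history
and host availability.

## Variable screening

`selectVariables()` reduces a candidate set by the transitive closure of
`|r| > 0.7` (keeping the best-scoring variable per cluster, score =
one-variable maxent training gain by default) and then iteratively drops
the worst-scoring variable with VIF > 10. The kept set always satisfies
both thresholds; ties resolve to the earlier variable in canonical order
so the procedure is deterministic. Expert inclusion lists (`keep =`)
override the automatic choice inside a cluster, mirroring the
biological-relevance override such studies apply by hand.

## Numerical choices and degenerate inputs

* Random numbers: every stage derives an independent 31-bit substream from
  the root seed and a stage name (`substreamSeed()`), so adding replicates
  to one stage never shifts another stage's draws; the global RNG state is
  restored after each call.
* Constant covariates are dropped from the feature map (with a note);
  constant expanded features are excluded from the solve.
* Beyond-range covariates are clamped; duplicated rows predict
  identically.
* Exact collinearity in VIF returns a large sentinel (1e12) rather than
  infinity; zero-variance variables are an error naming the variable.
* Empty high-severity subsets, empty buffers, empty masks, and all-zero
  weight vectors are errors with specific messages, because each one
  invalidates a specific modelling assumption rather than being missing
  data.
* Area summaries count cells at or above the threshold (default 0.5 on the
  cloglog scale, configurable and reported) times the cell area, in
  hectares.

## Limitations

* The background-weighting scheme constrains the model only where the
  weighted background retains mass. When the native model is nearly
  perfect and the regions coincide, the weights carve the background away
  exactly where the presences are, and the fitted quadratic can invert in
  the unoccupied extreme of the covariate space — predictions there are
  extrapolation. With a niche centred in availability this does not occur,
  and in the intended use case (an imperfect native model on a shifted
  region) the weights are far from degenerate; still, inspect response
  curves before interpreting weighted-model projections far outside the
  occupied climate.
* The next-year projection freezes coefficients and updates only the
  distance layers; it is a dispersal bookkeeping device, not a population
  model.
* Severity is linked to suitability through fixed cutpoints in the
  generator; this is an assumption for testing the severity-model
  machinery, not a claim about any real defoliator.
* ESRI ASCII grid is the only raster format read and written; coordinates
  are planar kilometres with cell centres, row 1 north.
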