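# invaniche

Niche models for invasive species that are **not yet at equilibrium** with
their new range.

A species distribution model calibrated only on an invader's occupied
range treats every unreached-but-suitable site as an absence, learns a
truncated niche, and transfers poorly. `invaniche` implements the
reciprocal-modelling workflow that addresses this: maximum-entropy climate
models fitted separately to the native and invaded ranges, a
native-model-informed weighting of invaded-range background points that
discounts likely "false absences", cross-region transfer evaluation with
AUC and the continuous Boyce index, and a regional layer of paired
distribution / severe-impact models built on landscape covariates (focal
cover statistics, patch fragmentation and heterogeneity, aspect classes,
dispersal-distance surfaces). A virtual-species simulator with known
generative truth backs the whole chain, so every claim the package makes
is tested against an oracle.

It is aimed at invasion ecologists and SDM methodologists who want the
weighting / transfer machinery as plain R functions with no external
binaries, and at anyone who needs a tested presence-background MaxEnt
implementation in base scientific R.

## The model

Covariates are standardized against the background sample and expanded to
linear + quadratic features f(x) (one-hot for categoricals). With
background base weights w(x), the fitted density is the Gibbs form

    q(x) = w(x) exp(λ·f(x)) / Z,   Z = Σ_b w(b) exp(λ·f(b)),

estimated by minimizing the penalized presence negative log-likelihood

    −(1/m) Σ_presences λ·f(x_i) + log Z + Σ_j ρ_j |λ_j|,
    ρ_j = β s_j / √m  (β = 3 by default),

with a FISTA solver to 1e-8 relative tolerance. Predictions use the
cloglog transform. The invaded-range "weighted" model attaches

    w(p) = 1 / (1 + (p/(1−p))²)

to each background point, where p is the native model's suitability there:
likely true absences keep full weight, unreached-but-suitable sites are
discounted. Presence terms are never weighted.

## Worked example

The reference experiment simulates one virtual species in two regions: a
native region sampled at equilibrium and an invaded region where a
dispersal-limited front occupies only part of the niche while suitable
patches remain unreached.

```r
library(invaniche)

scen  <- twoRegionScenario(seed = 1)
suite <- runClimateModels(scen$nativeOcc, scen$invadedOcc,
                          scen$native@climate, scen$invaded@climate,
                          config = studyConfig(seed = 1))
suite
#> modelSuite with models: clim_native, clim_invaded, clim_weighted
#>   native_calibration: AUC 0.893, CBI 0.879
#>   invaded_calibration: AUC 0.984, CBI 0.977
#>   weighted_calibration: AUC 0.984, CBI 0.947
#>   native_transfer: AUC 0.978, CBI 0.983
#>   invaded_transfer: AUC 0.85, CBI 0.735
#>   weighted_transfer: AUC 0.859, CBI 0.628
```

Reading the transfer rows: the invaded-only model drops from 0.984 at home
to 0.850 abroad — the truncation penalty — while the weighted model
transfers better (0.859) at essentially no cost at home (0.984), the
qualitative signature of background weighting. The same story shows in the
response-curve breadth of the truncated climate variable:

```r
sapply(suite$models, function(m)
  responseCurveWidth(responseCurve(m, "clim1")))
#>   clim_native  clim_invaded clim_weighted
#>          1.09          0.27          0.32
```

native ≥ weighted ≥ invaded: the weighted model recovers part of the niche
breadth the invaded-only model lost. The weight formula itself:

```r
gallienWeight(c(0, 0.25, 0.5, 0.75, 0.9))
#> [1] 1.0000 0.9000 0.5000 0.1000 0.0122
```

The regional layer (`regionalScenario()`, `buildRegionalCovariates()`,
`runRegionalModels()`, `projectNextYear()`) fits the paired
distribution/severity models with their buffered, host-masked "Reduced"
variants, emits permutation-based variable contributions and response
curves, and projects next-year maps by updating only the
distance-to-front covariates. `runFromConfig()` drives the whole chain
from a YAML file with a single seed and writes a manifest with file
digests; a thin command-line wrapper lives at `inst/cli/invaniche.R`.

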