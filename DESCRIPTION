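Package: invaniche
Title: Reciprocal Niche Modelling and Background Weighting for Invasive Species
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Presence-background maximum-entropy niche models for invasive
    species that are not yet at equilibrium with their new range. Implements
    an L1-penalised Gibbs (MaxEnt) model with linear and quadratic features,
    native-model-informed background weighting for non-equilibrium invaders,
    reciprocal cross-region transfer evaluation with AUC and the continuous
    Boyce index, landscape covariate construction (focal statistics, patch
    fragmentation and heterogeneity, aspect classes, minimum-distance
    surfaces), collinearity screening by Pearson correlation and variance
    inflation factors, and a virtual-species simulator with known generative
    truth for validating the whole chain on landscapes where the right
    answer is known.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'GridRaster-methods.R'
    'rng.R'
    'maxent-features.R'
    'maxent-fit.R'
    'geo-features.R'
    'background.R'
    'io.R'
    'synthetic-landscape.R'
    'maxent-interpret.R'
    'evaluation.R'
    'pipeline.R'
    'config.R'
    'variable-selection.R'
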