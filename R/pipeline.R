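#' @include background.R evaluation.R maxent-interpret.R synthetic-landscape.R
NULL

#' Study configuration defaults
#'
#' Collects the tunable settings of the model chain with the defaults used
#' throughout: 10,000 background points, 10 replicate 70/30 splits,
#' beta-multiplier 3 with linear+quadratic features, |r| > 0.7 and VIF > 10
#' screening thresholds, a 10 km buffer for the Reduced background design,
#' severity levels 3-4 counted as "high", and a 0.5 suitability threshold
#' for area summaries.
#'
#' @param seed root seed; every random stage derives a named substream.
#' @param ... overrides of any default.
#' @return a named list.
#' @export
studyConfig <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    nBackground = 10000,
    nReplicates = 10,
    trainFraction = 0.7,
    beta = 3,
    transform = "cloglog",
    rThreshold = 0.7,
    vifThreshold = 10,
    bufferKm = 10,
    highSeverity = 3,
    areaThreshold = 0.5,
    blockKm = 1,
    forestClasses = c(1, 2),
    nPermutations = 10
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

# mask of valid study cells: 1 where the reference climate layer is unmasked
.regionMask <- function(climate) {
  ref <- climate[[1L]]
  gridRaster((!is.na(ref@values)) * 1, ref@cellKm, ref@origin, "region")
}

# climate covariates at point locations
.extractStack <- function(stack, x, y) {
  out <- as.data.frame(lapply(stack, extractAt, px = x, py = y))
  names(out) <- names(stack)
  out
}

#' Reciprocal climate models with background weighting
#'
#' Fits the three-model comparison at the heart of the workflow:
#' `clim_native` on native-range occurrences with a uniform native
#' background, `clim_invaded` on invaded-range occurrences with a uniform
#' invaded background, and `clim_weighted` on the same invaded data but
#' with each invaded background point down-weighted by the native model's
#' suitability there ([gallienWeight()]). Produces calibration reports for
#' each model on its own region and the four reciprocal transfer reports.
#'
#' @param nativeOcc,invadedOcc occurrence data.frames (`x`, `y`, ...).
#' @param nativeClimate,invadedClimate named lists of climate
#'   [GridRaster-class] layers (same layer names in both regions).
#' @param config list from [studyConfig()].
#' @return a `modelSuite` list: `models` (ensembles), `evaluations`
#'   (calibration and transfer `evaluationReport`s), `data` (covariates,
#'   backgrounds, weights), `config`.
#' @export
runClimateModels <- function(nativeOcc, invadedOcc,
                             nativeClimate, invadedClimate,
                             config = studyConfig()) {
  if (!nrow(nativeOcc)) stop("native occurrence set is empty")
  if (!nrow(invadedOcc)) stop("invaded occurrence set is empty")
  bgN <- sampleBackground(.regionMask(nativeClimate), config$nBackground,
                          seed = substreamSeed(config$seed, "bg_native"))
  bgI <- sampleBackground(.regionMask(invadedClimate), config$nBackground,
                          seed = substreamSeed(config$seed, "bg_invaded"))
  covPresN <- .extractStack(nativeClimate, nativeOcc$x, nativeOcc$y)
  covPresI <- .extractStack(invadedClimate, invadedOcc$x, invadedOcc$y)
  covBgN <- .extractStack(nativeClimate, bgN$x, bgN$y)
  covBgI <- .extractStack(invadedClimate, bgI$x, bgI$y)
  fitArgs <- list(nReplicates = config$nReplicates,
                  trainFraction = config$trainFraction,
                  beta = config$beta, transform = config$transform)
  climNative <- do.call(replicateFit, c(
    list(covPresN, covBgN, seed = substreamSeed(config$seed, "fit_native")),
    fitArgs))
  climInvaded <- do.call(replicateFit, c(
    list(covPresI, covBgI, seed = substreamSeed(config$seed, "fit_invaded")),
    fitArgs))
  wdf <- weightBackground(covBgI, climNative)
  if (all(wdf$weight == 0))
    stop("all background weights are zero: the native model saturates the invaded region")
  climWeighted <- do.call(replicateFit, c(
    list(covPresI, covBgI, weights = wdf$weight,
         seed = substreamSeed(config$seed, "fit_weighted")),
    fitArgs))
  evals <- list(
    native_calibration = evaluateModel(climNative, covPresN, covBgN),
    invaded_calibration = evaluateModel(climInvaded, covPresI, covBgI),
    weighted_calibration = evaluateModel(climWeighted, covPresI, covBgI),
    native_transfer = transferReport(climNative, covPresI, covBgI),
    invaded_transfer = transferReport(climInvaded, covPresN, covBgN),
    weighted_transfer = transferReport(climWeighted, covPresN, covBgN)
  )
  structure(list(
    models = list(clim_native = climNative, clim_invaded = climInvaded,
                  clim_weighted = climWeighted),
    evaluations = evals,
    data = list(presNative = covPresN, presInvaded = covPresI,
                bgNative = covBgN, bgInvaded = covBgI,
                weights = wdf, bgPointsNative = bgN, bgPointsInvaded = bgI),
    config = config), class = "modelSuite")
}

#' @export
print.modelSuite <- function(x, ...) {
  cat("modelSuite with models: ", paste(names(x$models), collapse = ", "),
      "\n", sep = "")
  for (nm in names(x$evaluations)) {
    e <- x$evaluations[[nm]]
    cat("  ", nm, ": AUC ", signif(e$auc, 3), ", CBI ",
        signif(e$cbi, 3), "\n", sep = "")
  }
  invisible(x)
}

#' Build the regional covariate stack
#'
#' Assembles the covariates of the regional distribution and severity
#' models on the landscape grid: the weighted climate model's suitability
#' projection rescaled to percent, elevation, aspect categories, forest
#' cover and mean basal area within 1 km, per-km2 patch fragmentation and
#' heterogeneity, host cover within 10 km, and the minimum distance to the
#' previous year's records — all records for the distribution variant,
#' high-severity records only for the severity variant. Forest cells are
#' the configured habitat classes; basal area is a deterministic synthetic
#' stand proxy (declining with elevation on forest cells) since the
#' simulated landscape carries no inventory data.
#'
#' @param landscape a [LandscapeBundle-class]
#' @param climSuitability suitability [GridRaster-class] in (0, 1) (the
#'   weighted climate model projection).
#' @param occPrevYear previous-year occurrence data.frame.
#' @param variant `"distribution"` or `"severity"`.
#' @param config list from [studyConfig()].
#' @param basalArea optional basal-area [GridRaster-class] (m2/ha).
#' @return named list of [GridRaster-class] layers with attribute
#'   `categorical` naming the categorical layers and their levels.
#' @export
buildRegionalCovariates <- function(landscape, climSuitability, occPrevYear,
                                    variant = c("distribution", "severity"),
                                    config = studyConfig(),
                                    basalArea = NULL) {
  variant <- match.arg(variant)
  if (!nrow(occPrevYear)) stop("previous-year occurrence set is empty")
  if (variant == "severity") {
    n <- sum(occPrevYear$severity >= config$highSeverity)
    if (!n)
      stop("no high-severity (>= ", config$highSeverity,
           ") records for the severity distance layer")
  }
  cellKm <- cellSizeKm(landscape)
  hab <- landscape@habitat
  fv <- matrix(as.numeric(hab@values %in% config$forestClasses),
               nrow(hab@values))
  fv[is.na(hab@values)] <- NA_real_
  forest <- gridRaster(fv, cellKm, hab@origin, "forest")
  if (is.null(basalArea)) {
    ba <- 35 * forest@values * exp(-landscape@dem@values / 1000)
    basalArea <- gridRaster(ba, cellKm, hab@origin, "basal_area")
  }
  pm <- patchMetrics(hab, blockKm = config$blockKm)
  suitPct <- gridRaster(100 * climSuitability@values, cellKm,
                        hab@origin, "climate_suitability")
  dist <- if (variant == "distribution")
    minDistanceMap(occPrevYear, hab, units = "m")
  else minDistanceMap(occPrevYear, hab, minSeverity = config$highSeverity,
                      units = "m")
  stack <- list(
    climate_suitability = suitPct,
    elevation = landscape@dem,
    aspect = aspectCategory(landscape@dem),
    forest_cover_1km = focalPercentage(forest, 1, "forest_cover_1km"),
    basal_area_1km = focalMean(basalArea, 1, "basal_area_1km"),
    fragmentation = pm$fragmentation,
    heterogeneity = pm$heterogeneity,
    host_cover_10km = focalPercentage(landscape@host, 10, "host_cover_10km"),
    min_distance = dist
  )
  attr(stack, "categorical") <- list(aspect = 1:4)
  stack
}

# fit one regional ensemble from a stack, presence points and background
.fitRegional <- function(stack, occ, bgPoints, config, streamName,
                         dropVars = character()) {
  use <- setdiff(names(stack), dropVars)
  st <- stack[use]
  covPres <- .extractStack(st, occ$x, occ$y)
  covBg <- .extractStack(st, bgPoints$x, bgPoints$y)
  ok <- stats::complete.cases(covPres)
  covPres <- covPres[ok, , drop = FALSE]
  okb <- stats::complete.cases(covBg)
  covBg <- covBg[okb, , drop = FALSE]
  cats <- attr(stack, "categorical")
  cats <- cats[intersect(names(cats), use)]
  ens <- replicateFit(covPres, covBg,
                      nReplicates = config$nReplicates,
                      trainFraction = config$trainFraction,
                      beta = config$beta, transform = config$transform,
                      categorical = cats,
                      seed = substreamSeed(config$seed, streamName))
  list(ensemble = ens, presence = covPres, background = covBg)
}

#' Regional distribution and severity models with Reduced variants
#'
#' Fits four models: the distribution model (`dist`, all current-year
#' records) and the severity model (`sever`, high-severity records only),
#' each with a uniform background over the study region; and their Reduced
#' variants fitted with a background restricted to 10 km buffers around
#' the presences and masked to host cells, with the distance and
#' host-cover covariates removed — the design that asks what limits the
#' species beyond host availability and dispersal history. Contribution
#' tables and response curves are emitted for all four.
#'
#' @param occCurrent current-year occurrence data.frame.
#' @param covDist,covSever covariate stacks from
#'   [buildRegionalCovariates()] (distribution and severity variants).
#' @param hostMask binary host [GridRaster-class].
#' @param config list from [studyConfig()].
#' @return a `modelSuite` list with models `dist`, `sever`,
#'   `dist_reduced`, `sever_reduced`, their evaluations, contributions and
#'   response curves.
#' @export
runRegionalModels <- function(occCurrent, covDist, covSever, hostMask,
                              config = studyConfig()) {
  if (nrow(occCurrent) < 20)
    stop("at least 20 current-year occurrences are required")
  occHigh <- occCurrent[occCurrent$severity >= config$highSeverity, ,
                        drop = FALSE]
  if (!nrow(occHigh))
    stop("no high-severity occurrences for the severity model")
  grid <- covDist[[1L]]
  bgU <- sampleBackground(.regionMask(covDist), config$nBackground,
                          seed = substreamSeed(config$seed, "bg_regional"))
  bgDistR <- bufferedBackground(occCurrent, grid, config$bufferKm,
                                config$nBackground,
                                seed = substreamSeed(config$seed, "bg_dist_red"),
                                hostMask = hostMask)
  bgSevR <- bufferedBackground(occHigh, grid, config$bufferKm,
                               config$nBackground,
                               seed = substreamSeed(config$seed, "bg_sever_red"),
                               hostMask = hostMask)
  reducedDrop <- c("min_distance", "host_cover_10km")
  fits <- list(
    dist = .fitRegional(covDist, occCurrent, bgU, config, "fit_dist"),
    sever = .fitRegional(covSever, occHigh, bgU, config, "fit_sever"),
    dist_reduced = .fitRegional(covDist, occCurrent, bgDistR, config,
                                "fit_dist_red", reducedDrop),
    sever_reduced = .fitRegional(covSever, occHigh, bgSevR, config,
                                 "fit_sever_red", reducedDrop)
  )
  evals <- lapply(fits, function(f)
    evaluateModel(f$ensemble, f$presence, f$background))
  contribs <- lapply(fits, function(f)
    variableContribution(f$ensemble, f$presence, f$background,
                         nPermutations = config$nPermutations,
                         seed = substreamSeed(config$seed, "contrib")))
  curves <- lapply(fits, function(f) {
    vars <- names(.modelMap(f$ensemble)$variables)
    stats::setNames(lapply(vars, function(v)
      responseCurve(f$ensemble, v)), vars)
  })
  structure(list(
    models = lapply(fits, `[[`, "ensemble"),
    evaluations = evals,
    contributions = contribs,
    responseCurves = curves,
    data = lapply(fits, function(f) f[c("presence", "background")]),
    backgrounds = list(uniform = bgU, dist_reduced = bgDistR,
                       sever_reduced = bgSevR),
    config = config), class = "modelSuite")
}

#' Area above a suitability threshold
#'
#' Counts unmasked cells with prediction at or above the threshold and
#' converts to hectares (1 km2 = 100 ha).
#'
#' @param prediction suitability [GridRaster-class].
#' @param threshold suitability cutoff in (0, 1).
#' @param cellKm optional cell size override (default: the raster's).
#' @return area in hectares.
#' @export
areaSummary <- function(prediction, threshold, cellKm = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(cellKm)) cellKm <- prediction@cellKm
  n <- sum(prediction@values >= threshold, na.rm = TRUE)
  n * cellKm^2 * 100
}

#' Project the regional models to the next year
#'
#' Recomputes only the minimum-distance layers from the current year's
#' records, re-predicts with frozen model coefficients, masks the output
#' by the host distribution and summarizes the suitable area. No refit
#' happens: the projection isolates the effect of the advancing front on
#' the dispersal covariate.
#'
#' @param suite regional `modelSuite` from [runRegionalModels()].
#' @param occCurrent occurrence data.frame whose records define the new
#'   distance layers.
#' @param covDist,covSever the covariate stacks used to fit the suite.
#' @param hostMask binary host [GridRaster-class].
#' @param config list from [studyConfig()].
#' @return list with `predictions` (host-masked rasters per model) and
#'   `areasHa` (hectares at `config$areaThreshold`).
#' @export
projectNextYear <- function(suite, occCurrent, covDist, covSever, hostMask,
                            config = studyConfig()) {
  grid <- covDist[[1L]]
  covDist$min_distance <- minDistanceMap(occCurrent, grid, units = "m")
  occHigh <- occCurrent[occCurrent$severity >= config$highSeverity, ,
                        drop = FALSE]
  if (!nrow(occHigh))
    stop("no high-severity records to project the severity model")
  covSever$min_distance <- minDistanceMap(occHigh, grid, units = "m")
  stacks <- list(dist = covDist, sever = covSever,
                 dist_reduced = covDist[setdiff(names(covDist),
                   c("min_distance", "host_cover_10km"))],
                 sever_reduced = covSever[setdiff(names(covSever),
                   c("min_distance", "host_cover_10km"))])
  h <- hostMask@values
  preds <- lapply(names(suite$models), function(nm) {
    p <- ensemblePredict(suite$models[[nm]], stacks[[nm]])
    v <- p@values
    v[is.na(h) | h == 0] <- NA_real_
    p@values <- v
    p
  })
  names(preds) <- names(suite$models)
  areas <- vapply(preds, areaSummary, numeric(1),
                  threshold = config$areaThreshold)
  list(predictions = preds, areasHa = areas)
}

#' Two-region truncated-niche study scenario
#'
#' The reference synthetic experiment: one virtual species with a
#' quadratic climate niche, a native region where it is sampled at
#' equilibrium, and an invaded region whose climate availability is
#' shifted so the introduced population occupies only part of the niche,
#' sampled along a dispersal-limited invasion front. Both regions share
#' the generative truth on an absolute scale, so native-model transfer,
#' background weighting and niche-truncation diagnostics can be measured
#' against known ground truth.
#'
#' @param seed integer root seed.
#' @param nRow,nCol,cellKm grid geometry per region.
#' @param nVars number of climate layers (niche on the first two).
#' @param shift climate shift (in sd units) applied to the first layer of
#'   the invaded region; controls how truncated the invaded niche is.
#' @param nNative equilibrium records in the native region.
#' @param nYears,perYearIntensity invasion-front simulation settings.
#' @param autocorrRangeKm climate autocorrelation range (km).
#' @return list with `truth`, `native`/`invaded` [LandscapeBundle-class]s,
#'   `nativeOcc`/`invadedOcc`, and the true-suitability rasters.
#' @export
twoRegionScenario <- function(seed = 1, nRow = 120, nCol = 120, cellKm = 1,
                              nVars = 4, shift = -0.8, nNative = 400,
                              nYears = 5, perYearIntensity = 70,
                              autocorrRangeKm = 12) {
  corMat <- diag(nVars)
  corMat[1, 2] <- corMat[2, 1] <- 0.3
  vars <- paste0("clim", seq_len(nVars))
  a1 <- stats::setNames(rep(0, nVars), vars)
  a2 <- stats::setNames(rep(0, nVars), vars)
  # niche optimum off-centre of availability (clim1 = 2): only the upper
  # tail of the region is suitable, giving a well-defined narrow niche
  a1["clim1"] <- 12
  a2["clim1"] <- -3
  a1["clim2"] <- 0.5
  a2["clim2"] <- -0.5
  truth <- virtualSpeciesTruth(a0 = -10, a1 = a1, a2 = a2,
                               hostDependent = FALSE,
                               dispersalRadiusKm = 8,
                               seed = substreamSeed(seed, "truth"))
  native <- makeLandscape(nRow, nCol, cellKm, corMat, autocorrRangeKm,
                          hostPrevalence = 0.4,
                          seed = substreamSeed(seed, "native_land"),
                          climNames = vars)
  invaded <- makeLandscape(nRow, nCol, cellKm, corMat, autocorrRangeKm,
                           hostPrevalence = 0.4,
                           seed = substreamSeed(seed, "invaded_land"),
                           climNames = vars)
  # shift the invaded availability of clim1 downward: suitable climates
  # exist there but only in scattered far patches of the upper tail
  sh <- invaded@climate[["clim1"]]
  sh@values <- sh@values + shift
  invaded@climate[["clim1"]] <- sh
  suitNative <- trueSuitability(truth, native@climate, center = 0, scale = 1)
  suitInvaded <- trueSuitability(truth, invaded@climate, center = 0, scale = 1)
  nativeOcc <- sampleOccurrencesEquilibrium(truth, native, nNative,
    seed = substreamSeed(seed, "native_occ"), suitability = suitNative)
  # introduce the invader on the lower flank of its niche (below the
  # optimum), so the dispersal-limited front realizes a truncated niche
  # even though fully suitable climates exist elsewhere in the region
  w <- .samplingWeights(truth, invaded, suitInvaded)
  clim1v <- invaded@climate[["clim1"]]@values
  flank <- w > 0.1 & clim1v < 1.4
  introCell <- if (any(flank)) which(flank)[which.max(w[flank])]
               else which.max(w)
  intro <- cellCenters(suitInvaded, introCell)
  invadedOcc <- simulateInvasion(truth, invaded, intro, nYears,
    perYearIntensity, seed = substreamSeed(seed, "invasion"),
    suitability = suitInvaded)
  list(truth = truth, native = native, invaded = invaded,
       nativeOcc = nativeOcc, invadedOcc = invadedOcc,
       suitNative = suitNative, suitInvaded = suitInvaded)
}

#' Single-region invasion scenario for the regional models
#'
#' Generates one landscape with a host-dependent virtual species and a
#' multi-year dispersal-limited invasion, split into previous-year records
#' (which define the dispersal distance covariates) and current-year
#' records (the calibration presences), emulating the two-season regional
#' data design. Severity is linked to true climate suitability through the
#' truth's cutpoints, so severe impact concentrates where climate is
#' favourable. The true suitability raster is returned for use as the
#' climate-suitability covariate, conditioning the regional experiment on
#' an exact climate layer rather than an estimated one.
#'
#' @param seed integer root seed.
#' @param nRow,nCol,cellKm grid geometry (default 160 x 160 at 0.5 km).
#' @param nYears simulated years (default 6).
#' @param perYearIntensity target new records per year (default 150).
#' @param hostPrevalence host cell fraction (default 0.25).
#' @return list with `truth`, `landscape`, `suitability`, `occPrev`
#'   (years before the last) and `occCurrent` (final year).
#' @export
regionalScenario <- function(seed = 1, nRow = 160, nCol = 160, cellKm = 0.5,
                             nYears = 6, perYearIntensity = 150,
                             hostPrevalence = 0.25) {
  nVars <- 4
  corMat <- diag(nVars)
  corMat[1, 2] <- corMat[2, 1] <- 0.3
  vars <- paste0("clim", seq_len(nVars))
  a1 <- stats::setNames(c(1.5, 0.5, 0, 0), vars)
  a2 <- stats::setNames(c(-1.5, -0.5, 0, 0), vars)
  truth <- virtualSpeciesTruth(a0 = 1, a1 = a1, a2 = a2,
                               hostDependent = TRUE,
                               dispersalRadiusKm = 8,
                               seed = substreamSeed(seed, "truth"))
  landscape <- makeLandscape(nRow, nCol, cellKm, corMat,
                             autocorrRangeKm = 6,
                             hostPrevalence = hostPrevalence,
                             clusteringRangeKm = 2,
                             seed = substreamSeed(seed, "land"),
                             climNames = vars)
  suit <- trueSuitability(truth, landscape@climate, center = 0, scale = 1)
  w <- .samplingWeights(truth, landscape, suit)
  intro <- cellCenters(suit, which.max(w))
  occ <- simulateInvasion(truth, landscape, intro, nYears,
                          perYearIntensity,
                          seed = substreamSeed(seed, "invasion"),
                          startYear = 2014L, suitability = suit)
  lastYear <- max(occ$year)
  list(truth = truth, landscape = landscape, suitability = suit,
       occPrev = occ[occ$year < lastYear, , drop = FALSE],
       occCurrent = occ[occ$year == lastYear, , drop = FALSE])
}
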