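#' @import methods
NULL

#' GridRaster: a regular planar grid of cell values
#'
#' The common currency of all spatial layers in this package: a numeric
#' matrix on a regular grid with a cell edge length in kilometres and a
#' planar origin. Row 1 is the northernmost row and column 1 the westernmost
#' column; `NA` cells are masked (outside the study area). Coordinates are
#' planar kilometres; the origin is the lower-left corner of the grid, so a
#' cell centre sits at `origin + (col - 0.5, nrow - row + 0.5) * cellKm`.
#'
#' @slot values numeric matrix of cell values; `NA` encodes the mask.
#' @slot cellKm cell edge length in km (single positive number).
#' @slot origin numeric length-2, x/y of the lower-left grid corner in km.
#' @slot name layer name used in stacks and file output.
#'
#' @aliases GridRaster-class
#' @exportClass GridRaster
setClass("GridRaster",
  representation(
    values = "matrix",
    cellKm = "numeric",
    origin = "numeric",
    name   = "character"
  ),
  prototype(cellKm = 1, origin = c(0, 0), name = "layer")
)

setValidity("GridRaster", function(object) {
  msg <- character()
  if (!is.numeric(object@values) && !is.logical(object@values))
    msg <- c(msg, "'values' must be a numeric matrix")
  if (length(object@cellKm) != 1L || !is.finite(object@cellKm) ||
      object@cellKm <= 0)
    msg <- c(msg, "'cellKm' must be a single positive number")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be two finite numbers")
  if (length(object@name) != 1L)
    msg <- c(msg, "'name' must be a single string")
  if (length(msg)) msg else TRUE
})

#' LandscapeBundle: co-registered landscape layers
#'
#' Bundles everything the niche models consume about one study region: a
#' stack of climate layers, a binary host-plant raster, an integer habitat
#' class raster and a digital elevation model, all on one shared grid.
#'
#' @slot climate named list of [GridRaster-class] climate layers.
#' @slot host binary [GridRaster-class] (1 = host plant present).
#' @slot habitat integer-class [GridRaster-class] (classes `1..C`).
#' @slot dem elevation [GridRaster-class] in metres.
#'
#' @aliases LandscapeBundle-class
#' @exportClass LandscapeBundle
setClass("LandscapeBundle",
  representation(
    climate = "list",
    host    = "GridRaster",
    habitat = "GridRaster",
    dem     = "GridRaster"
  )
)

.sameGeometry <- function(a, b) {
  identical(dim(a@values), dim(b@values)) &&
    isTRUE(all.equal(a@cellKm, b@cellKm)) &&
    isTRUE(all.equal(a@origin, b@origin))
}

setValidity("LandscapeBundle", function(object) {
  msg <- character()
  if (length(object@climate) < 1L)
    msg <- c(msg, "at least one climate layer is required")
  if (is.null(names(object@climate)) || anyDuplicated(names(object@climate)))
    msg <- c(msg, "climate layers must have unique names")
  for (r in object@climate)
    if (!is(r, "GridRaster")) msg <- c(msg, "climate entries must be GridRaster")
  ref <- object@climate[[1L]]
  for (r in c(object@climate, list(object@host, object@habitat, object@dem)))
    if (is(r, "GridRaster") && !.sameGeometry(ref, r)) {
      msg <- c(msg, "all layers must share grid dimensions, cell size and origin")
      return(msg)   # geometry broken: later elementwise checks cannot run
    }
  hv <- object@host@values
  if (!all(hv[!is.na(hv)] %in% c(0, 1)))
    msg <- c(msg, "host raster must be binary 0/1")
  # host can only occur on unmasked climate cells
  if (any(hv == 1 & is.na(ref@values), na.rm = TRUE))
    msg <- c(msg, "host cells must lie inside the unmasked study area")
  cl <- object@habitat@values
  cls <- sort(unique(cl[!is.na(cl)]))
  if (length(cls) && (any(cls != round(cls)) || any(cls < 1)))
    msg <- c(msg, "habitat classes must be positive integers")
  if (length(msg)) msg else TRUE
})

#' VirtualSpeciesTruth: generative niche parameters
#'
#' The known truth behind a simulated species: a logistic-quadratic niche
#' over standardized climate layers, an optional host-plant dependence, a
#' yearly dispersal radius and ordered severity cutpoints that map true
#' suitability to a 4-level impact score. Serves as the oracle when testing
#' whether fitted models recover the niche.
#'
#' @slot a0 intercept of the linear predictor.
#' @slot a1 named per-variable linear coefficients.
#' @slot a2 named per-variable quadratic coefficients, all `<= 0`.
#' @slot hostDependent if `TRUE`, occurrence requires the host plant.
#' @slot dispersalRadiusKm maximum yearly spread distance (km).
#' @slot severityCutpoints three increasing thresholds in (0,1) splitting
#'   suitability into severity levels 1-4.
#' @slot seed integer seed recorded with the truth.
#'
#' @aliases VirtualSpeciesTruth-class
#' @exportClass VirtualSpeciesTruth
setClass("VirtualSpeciesTruth",
  representation(
    a0 = "numeric",
    a1 = "numeric",
    a2 = "numeric",
    hostDependent = "logical",
    dispersalRadiusKm = "numeric",
    severityCutpoints = "numeric",
    seed = "integer"
  ),
  prototype(hostDependent = TRUE, dispersalRadiusKm = 10,
            severityCutpoints = c(0.25, 0.5, 0.75), seed = 1L)
)

setValidity("VirtualSpeciesTruth", function(object) {
  msg <- character()
  if (length(object@a0) != 1L) msg <- c(msg, "'a0' must be a single number")
  if (length(object@a1) != length(object@a2) ||
      !identical(names(object@a1), names(object@a2)))
    msg <- c(msg, "'a1' and 'a2' must be equally named vectors")
  if (is.null(names(object@a1)) && length(object@a1))
    msg <- c(msg, "'a1'/'a2' must be named by climate layer")
  if (any(object@a2 > 0))
    msg <- c(msg, "quadratic coefficients must be <= 0 (unimodal niche)")
  cp <- object@severityCutpoints
  if (length(cp) != 3L || any(diff(cp) <= 0) || any(cp <= 0) || any(cp >= 1))
    msg <- c(msg, "'severityCutpoints' must be 3 strictly increasing values in (0,1)")
  if (length(msg)) msg else TRUE
})

#' MaxentModel: a fitted maximum-entropy niche model
#'
#' Coefficients of the L1-penalised Gibbs density over linear + quadratic
#' (and one-hot categorical) features, together with the feature map used to
#' standardize and clamp covariates, the training partition constant and the
#' output transform.
#'
#' @slot coef named coefficient vector over expanded features.
#' @slot beta the global regularization multiplier.
#' @slot regScale named per-feature L1 penalty scale (`beta * s_j / sqrt(m)`).
#' @slot featureMap list describing per-variable standardization constants,
#'   clamping bounds and expansion rule (see [buildFeatureMap()]).
#' @slot logZ log partition constant over the (weighted) training background.
#' @slot entropy entropy of the fitted density over the training background;
#'   drives the cloglog/logistic output transforms.
#' @slot transform one of `"cloglog"`, `"logistic"`, `"raw"`.
#' @slot meta list of training metadata (seed, replicate id, counts).
#'
#' @aliases MaxentModel-class
#' @exportClass MaxentModel
setClass("MaxentModel",
  representation(
    coef = "numeric",
    beta = "numeric",
    regScale = "numeric",
    featureMap = "list",
    logZ = "numeric",
    entropy = "numeric",
    transform = "character",
    meta = "list"
  ),
  prototype(beta = 3, transform = "cloglog", meta = list())
)

setValidity("MaxentModel", function(object) {
  msg <- character()
  if (any(!is.finite(object@coef))) msg <- c(msg, "coefficients must be finite")
  if (!object@transform %in% c("cloglog", "logistic", "raw"))
    msg <- c(msg, "transform must be cloglog, logistic or raw")
  if (length(object@beta) != 1L || object@beta < 0)
    msg <- c(msg, "'beta' must be a single nonnegative number")
  if (length(msg)) msg else TRUE
})

#' MaxentEnsemble: replicate-averaged model
#'
#' A set of replicate [MaxentModel-class] fits from independent 70/30
#' presence splits sharing one background, predicted by averaging the
#' replicate outputs, plus the per-replicate held-out evaluation.
#'
#' @slot models list of [MaxentModel-class] replicates.
#' @slot evaluation data.frame with one row per replicate (auc, cbi, counts).
#' @slot meta list: seed, train fraction, replicate count.
#'
#' @aliases MaxentEnsemble-class
#' @exportClass MaxentEnsemble
setClass("MaxentEnsemble",
  representation(models = "list", evaluation = "data.frame", meta = "list"),
  prototype(meta = list())
)

setValidity("MaxentEnsemble", function(object) {
  msg <- character()
  if (!length(object@models)) msg <- c(msg, "at least one replicate required")
  for (m in object@models)
    if (!is(m, "MaxentModel")) { msg <- c(msg, "models must be MaxentModel"); break }
  if (length(msg)) msg else TRUE
})

#' Validate an occurrence table
#'
#' Occurrence records are plain data.frames with columns `x`, `y` (planar
#' km), `year` (integer), `severity` (1-4) and `source` (free-text
#' provenance tag, e.g. `"equilibrium"` or `"invasion"`). This checks the
#' schema and the no-duplicate-location invariant.
#'
#' @param occ data.frame of occurrence records.
#' @param landscape optional [LandscapeBundle-class]; when given, coordinates
#'   must fall on its extent.
#' @return `occ`, invisibly, after validation.
#' @export
validateOccurrences <- function(occ, landscape = NULL) {
  need <- c("x", "y", "year", "severity", "source")
  if (!all(need %in% names(occ)))
    stop("occurrence table must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(occ$x)) || any(!is.finite(occ$y)))
    stop("occurrence coordinates must be finite")
  if (!all(occ$severity %in% 1:4))
    stop("severity must be an integer in 1..4")
  if (anyDuplicated(occ[, c("x", "y", "year")]))
    stop("duplicate (x, y, year) records are not allowed")
  if (!is.null(landscape)) {
    ref <- landscape@climate[[1L]]
    ext <- c(ref@origin[1], ref@origin[1] + ncol(ref@values) * ref@cellKm,
             ref@origin[2], ref@origin[2] + nrow(ref@values) * ref@cellKm)
    if (any(occ$x < ext[1] | occ$x > ext[2] | occ$y < ext[3] | occ$y > ext[4]))
      stop("occurrences fall outside the landscape extent")
  }
  invisible(occ)
}
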