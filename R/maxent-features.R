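#' @include GridRaster-methods.R
NULL

#' Build a feature map from a background sample
#'
#' Continuous covariates are standardized with the background mean and sd
#' and expanded to a linear (`z`) and a quadratic (`z^2`) feature; values
#' are clamped to the background min/max before expansion, which fixes the
#' model's behaviour when projecting beyond the training range. Categorical
#' covariates expand to one indicator per declared level; an undeclared
#' code (e.g. the flat aspect class, 0) maps to all-zero indicators.
#' Constant covariates are dropped with a note in the map.
#'
#' @param background data.frame of background covariates.
#' @param categorical named list: for each categorical variable, the vector
#'   of levels that get indicators (e.g. `list(aspect = 1:4)`).
#' @return feature map list with elements `variables` (per-variable specs),
#'   `features` (expanded feature names), `featureSd` (background sd per
#'   expanded feature) and `dropped`.
#' @export
buildFeatureMap <- function(background, categorical = list()) {
  vars <- names(background)
  specs <- list()
  dropped <- character()
  for (v in vars) {
    x <- background[[v]]
    if (any(!is.finite(x)))
      stop("non-finite values in background covariate '", v, "'")
    if (v %in% names(categorical)) {
      specs[[v]] <- list(type = "categorical", levels = categorical[[v]])
    } else {
      s <- stats::sd(x)
      if (!is.finite(s) || s <= 1e-12) {
        dropped <- c(dropped, v)
        next
      }
      specs[[v]] <- list(type = "continuous", mean = mean(x), sd = s,
                         min = min(x), max = max(x))
    }
  }
  if (!length(specs)) stop("no usable covariates (all constant)")
  map <- list(variables = specs, dropped = dropped)
  F <- expandFeatures(map, background)
  map$features <- colnames(F)
  map$featureSd <- apply(F, 2, stats::sd)
  map
}

#' Expand covariates into model features
#'
#' Applies a feature map: clamps continuous covariates to the training
#' bounds, standardizes, and emits linear + quadratic columns; categorical
#' covariates emit one-hot indicator columns.
#'
#' @param map feature map from [buildFeatureMap()].
#' @param data data.frame of covariates containing every mapped variable.
#' @return numeric feature matrix (rows = observations).
#' @export
expandFeatures <- function(map, data) {
  cols <- list()
  for (v in names(map$variables)) {
    if (!v %in% names(data))
      stop("covariate '", v, "' is missing from the data")
    spec <- map$variables[[v]]
    x <- data[[v]]
    if (any(!is.finite(x)))
      stop("non-finite values in covariate '", v, "'")
    if (spec$type == "continuous") {
      x <- pmin(pmax(x, spec$min), spec$max)
      z <- (x - spec$mean) / spec$sd
      cols[[v]] <- z
      cols[[paste0(v, "^2")]] <- z^2
    } else {
      for (lev in spec$levels)
        cols[[paste0(v, "==", lev)]] <- as.numeric(x == lev)
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- names(cols)
  out
}

# variable that owns an expanded feature name
.featureVariable <- function(feature) {
  sub("(\\^2|==.*)$", "", feature)
}
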