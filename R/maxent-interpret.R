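#' @include maxent-fit.R
NULL

.modelMap <- function(x) {
  if (is(x, "MaxentEnsemble")) x@models[[1L]]@featureMap else x@featureMap
}

.modelPredict <- function(x, newdata) {
  if (is(x, "MaxentEnsemble")) ensemblePredict(x, newdata)
  else maxentPredict(x, newdata)
}

#' Permutation-based variable contributions
#'
#' Importance of each model variable as the drop in presence/background AUC
#' when that variable's values are permuted across the evaluation rows
#' (both expanded features of a continuous variable move jointly because
#' the raw covariate is permuted before expansion). Drops are averaged over
#' `nPermutations` permutations, floored at zero and normalized to sum to
#' 100.
#'
#' @param model a [MaxentModel-class] or [MaxentEnsemble-class]
#' @param presence,background covariate data.frames used for evaluation.
#' @param nPermutations permutations per variable (default 10).
#' @param seed integer seed for the permutations.
#' @return named numeric vector of percentages summing to 100.
#' @export
variableContribution <- function(model, presence, background,
                                 nPermutations = 10, seed = 1) {
  map <- .modelMap(model)
  vars <- names(map$variables)
  allData <- rbind(presence[, vars, drop = FALSE],
                   background[, vars, drop = FALSE])
  np <- nrow(presence)
  idxP <- seq_len(np)
  base <- aucScore(.modelPredict(model, allData[idxP, , drop = FALSE]),
                   .modelPredict(model, allData[-idxP, , drop = FALSE]))
  drops <- withSubstream(seed, "permutation", {
    vapply(vars, function(v) {
      d <- vapply(seq_len(nPermutations), function(k) {
        perm <- allData
        perm[[v]] <- perm[[v]][sample.int(nrow(perm))]
        base - aucScore(.modelPredict(model, perm[idxP, , drop = FALSE]),
                        .modelPredict(model, perm[-idxP, , drop = FALSE]))
      }, numeric(1))
      mean(d)
    }, numeric(1))
  })
  drops <- pmax(drops, 0)
  if (sum(drops) <= 0) {
    # no variable moves the AUC: attribute evenly rather than divide by 0
    out <- rep(100 / length(vars), length(vars))
    names(out) <- vars
    return(out)
  }
  100 * drops / sum(drops)
}

#' Marginal response curve of one variable
#'
#' Sweeps the variable across its training-background range with all other
#' continuous variables fixed at their background means (categoricals at
#' the reference all-zero code) and returns the predicted suitability. For
#' an ensemble the replicate predictions are averaged. Categorical
#' variables yield one prediction per level instead of a sweep.
#'
#' @param model a [MaxentModel-class] or [MaxentEnsemble-class]
#' @param variable model variable name.
#' @param nPoints sweep resolution (default 100).
#' @return data.frame with `value` (or `level`) and `suitability`.
#' @export
responseCurve <- function(model, variable, nPoints = 100) {
  map <- .modelMap(model)
  if (!variable %in% names(map$variables))
    stop("'", variable, "' is not a model variable")
  spec <- map$variables[[variable]]
  ref <- lapply(map$variables, function(s) {
    if (s$type == "continuous") s$mean
    else if (!0 %in% s$levels) 0 else s$levels[1L]
  })
  if (spec$type == "categorical") {
    out <- lapply(spec$levels, function(lev) {
      row <- ref
      row[[variable]] <- lev
      data.frame(level = lev,
                 suitability = .modelPredict(model, as.data.frame(row)))
    })
    return(do.call(rbind, out))
  }
  values <- seq(spec$min, spec$max, length.out = nPoints)
  grid <- as.data.frame(ref)[rep(1L, nPoints), , drop = FALSE]
  grid[[variable]] <- values
  data.frame(value = values,
             suitability = .modelPredict(model, grid))
}

#' Breadth of a response curve
#'
#' The length of the swept variable range over which the curve rises above
#' `frac` of its own amplitude (minimum plus `frac` times the range). Used
#' to compare how broad a niche different models assign to one variable;
#' a model trained on a truncated sample both sweeps and responds over a
#' narrower range.
#'
#' @param curve data.frame from [responseCurve()] (continuous variable).
#' @param frac amplitude fraction defining "supported" (default 0.5).
#' @return width in the variable's units.
#' @export
responseCurveWidth <- function(curve, frac = 0.5) {
  s <- curve$suitability
  if (max(s) - min(s) < 1e-12) return(diff(range(curve$value)))
  thr <- min(s) + frac * (max(s) - min(s))
  keep <- s >= thr
  if (!any(keep)) return(0)
  dv <- mean(diff(curve$value))
  sum(keep) * dv
}
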