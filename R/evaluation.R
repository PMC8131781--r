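#' @include maxent-fit.R
NULL

#' Presence/background AUC
#'
#' Mann-Whitney estimator: the fraction of (presence, background) score
#' pairs where the presence scores higher, ties counted one half. Computed
#' from ranks, so it matches exact pair counting at any size.
#'
#' @param presenceScores,backgroundScores numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @examples
#' aucScore(c(0.8, 0.3), c(0.5, 0.1))  # 0.75
#' @export
aucScore <- function(presenceScores, backgroundScores) {
  np <- length(presenceScores)
  nb <- length(backgroundScores)
  if (!np || !nb) stop("both score sets must be non-empty")
  r <- rank(c(presenceScores, backgroundScores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Continuous Boyce index
#'
#' Slides `nWindows` overlapping windows of width `windowWidthFraction`
#' times the score range across the range of the scores. Per window, `P` is
#' the proportion of presence scores inside and `E` the proportion of
#' landscape (background) scores inside; the index is the Spearman rank
#' correlation between the window centre and the `P/E` ratio over windows
#' with `E > 0`. Positive values mean higher-suitability classes hold
#' disproportionately many presences; +1 is a perfectly consistent
#' ranking, 0 a random model, negative values an inverted one.
#'
#' @param presenceScores scores at presence points.
#' @param landscapeScores scores of the available landscape (background
#'   sample or all cells).
#' Consecutive duplicated `P/E` values are collapsed to one before the
#' correlation (the convention of the reference implementations), so runs
#' of empty windows do not dilute the rank correlation. The default window
#' width (2% of the score range) keeps roughly 50 effectively independent
#' windows, which keeps the index near zero for a random model; both
#' window parameters are recorded in every report.
#'
#' @param nWindows number of window centres (default 101).
#' @param windowWidthFraction window width as a fraction of the score
#'   range (default 0.02).
#' @return list with `cbi`, the `curve` data.frame (center, P, E, PE) and
#'   the window parameters.
#' @export
continuousBoyceIndex <- function(presenceScores, landscapeScores,
                                 nWindows = 101,
                                 windowWidthFraction = 0.02) {
  if (!length(presenceScores) || !length(landscapeScores))
    stop("both score sets must be non-empty")
  rng <- range(c(presenceScores, landscapeScores))
  if (diff(rng) < 1e-12)
    stop("scores are constant; the Boyce index is undefined")
  half <- windowWidthFraction * diff(rng) / 2
  centers <- seq(rng[1], rng[2], length.out = nWindows)
  P <- E <- numeric(nWindows)
  for (i in seq_len(nWindows)) {
    lo <- centers[i] - half
    hi <- centers[i] + half
    P[i] <- mean(presenceScores >= lo & presenceScores <= hi)
    E[i] <- mean(landscapeScores >= lo & landscapeScores <= hi)
  }
  usable <- E > 0
  if (sum(usable) < 3)
    stop("fewer than 3 windows contain landscape scores")
  pe <- P[usable] / E[usable]
  ctr <- centers[usable]
  keep <- !duplicated(pe)          # collapse runs of identical P/E
  cbi <- suppressWarnings(
    stats::cor(ctr[keep], pe[keep], method = "spearman"))
  list(cbi = cbi,
       curve = data.frame(center = centers, P = P, E = E,
                          PE = ifelse(E > 0, P / E, NA_real_)),
       nWindows = nWindows, windowWidthFraction = windowWidthFraction)
}

#' Evaluate a fitted model on presence and background covariates
#'
#' Predicts both sets and reports AUC and the continuous Boyce index. A
#' constant prediction is flagged degenerate (AUC 0.5, CBI `NA`) rather
#' than erroring, since regularization can legitimately flatten a model.
#'
#' @param model a [MaxentModel-class] or [MaxentEnsemble-class]
#' @param presence,background covariate data.frames.
#' @param region tag recorded in the report: `"calibration"` or
#'   `"transfer"`.
#' @param nWindows,windowWidthFraction CBI window parameters.
#' @return an `evaluationReport` list: `auc`, `cbi`, `nPresenceEval`,
#'   `nBackgroundEval`, `region`, `degenerate`, window parameters, and the
#'   P/E `curve`.
#' @export
evaluateModel <- function(model, presence, background,
                          region = "calibration", nWindows = 101,
                          windowWidthFraction = 0.02) {
  ps <- .modelPredict(model, presence)
  bs <- .modelPredict(model, background)
  degenerate <- diff(range(c(ps, bs))) < 1e-12
  auc <- aucScore(ps, bs)
  if (degenerate) {
    cbi <- NA_real_
    curve <- NULL
  } else {
    b <- tryCatch(
      continuousBoyceIndex(ps, bs, nWindows, windowWidthFraction),
      error = function(e) NULL)
    cbi <- if (is.null(b)) NA_real_ else b$cbi
    curve <- if (is.null(b)) NULL else b$curve
  }
  structure(list(auc = auc, cbi = cbi,
                 nPresenceEval = length(ps), nBackgroundEval = length(bs),
                 region = region, degenerate = degenerate,
                 nWindows = nWindows,
                 windowWidthFraction = windowWidthFraction,
                 curve = curve),
            class = "evaluationReport")
}

#' @export
print.evaluationReport <- function(x, ...) {
  cat("Evaluation (", x$region, "): AUC = ", signif(x$auc, 3),
      ", CBI = ", signif(x$cbi, 3),
      if (x$degenerate) " [degenerate: constant prediction]" else "",
      "\n  n = ", x$nPresenceEval, " presences vs ", x$nBackgroundEval,
      " background\n", sep = "")
  invisible(x)
}

#' Transfer evaluation on another region's data
#'
#' [evaluateModel()] with the region tag set to `"transfer"`: the model is
#' scored on presences and background from a region it was not calibrated
#' on, the reciprocal-projection check used to diagnose niche truncation.
#'
#' @param model a [MaxentModel-class] or [MaxentEnsemble-class]
#' @param presence,background covariate data.frames from the other region.
#' @param ... passed to [evaluateModel()].
#' @return an `evaluationReport`.
#' @export
transferReport <- function(model, presence, background, ...) {
  evaluateModel(model, presence, background, region = "transfer", ...)
}
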