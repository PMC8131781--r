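#' @include GridRaster-methods.R
NULL

#' Pearson correlation matrix of candidate variables
#'
#' @param samples matrix or data.frame, samples by variables.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearsonMatrix <- function(samples) {
  X <- as.matrix(samples)
  if (nrow(X) < 3) stop("at least 3 samples are required")
  if (ncol(X) < 2) stop("at least 2 variables are required")
  sds <- apply(X, 2, stats::sd)
  if (any(sds <= 1e-12))
    stop("zero-variance variable(s): ",
         paste(colnames(X)[sds <= 1e-12], collapse = ", "))
  stats::cor(X)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the least-squares
#' regression of variable `j` on all the others. Exactly collinear
#' variables (`R^2 >= 1 - 1e-12`) are capped at a large sentinel (`1e12`)
#' so they are flagged rather than producing infinities.
#'
#' @param samples matrix or data.frame, samples by variables.
#' @return named numeric vector of VIFs.
#' @export
vifScores <- function(samples) {
  X <- as.matrix(samples)
  p <- ncol(X)
  if (nrow(X) <= p) stop("more samples than variables are required")
  if (p < 2) return(stats::setNames(1, colnames(X)))
  out <- numeric(p)
  for (j in seq_len(p)) {
    y <- X[, j]
    tss <- sum((y - mean(y))^2)
    if (tss <= 1e-24)
      stop("zero-variance variable: ", colnames(X)[j])
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), y)
    r2 <- 1 - sum(fit$residuals^2) / tss
    out[j] <- if (r2 >= 1 - 1e-12) 1e12 else 1 / (1 - r2)
  }
  names(out) <- colnames(X)
  out
}

# connected components of the |r| > threshold graph (transitive closure)
.corClusters <- function(corMat, threshold) {
  p <- ncol(corMat)
  adj <- abs(corMat) > threshold
  diag(adj) <- FALSE
  comp <- integer(p)
  cur <- 0L
  for (s in seq_len(p)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  split(colnames(corMat), comp)
}

#' Collinearity screening of candidate variables
#'
#' Two-stage greedy reduction mirroring standard bioclimatic-variable
#' screening: (1) cluster variables by the transitive closure of
#' `|r| > rThreshold` and keep the best-scoring variable of each cluster;
#' (2) iteratively drop the worst-scoring remaining variable whose VIF
#' exceeds `vifThreshold` until all pass. Scores default to the training
#' gain of a one-variable maxent fit when `presence` is supplied (see
#' [maxentGainScorer()]); with no scorer and no presences all scores are
#' equal and ties resolve to the earlier variable in column order.
#'
#' @param samples matrix or data.frame of screening samples by variables
#'   (typically the background covariates).
#' @param rThreshold pairwise correlation threshold (default 0.7).
#' @param vifThreshold VIF threshold (default 10).
#' @param scorer optional `function(variable) -> score`.
#' @param presence optional presence covariates for the default scorer.
#' @param keep variables never dropped (manual biological override).
#' @return a selection report: list with `correlation`, `vif` (on the
#'   candidates), `vifKept` (on the kept set), `clusters`, `kept`,
#'   `dropped` (data.frame of variable/reason), `scores`.
#' @export
selectVariables <- function(samples, rThreshold = 0.7, vifThreshold = 10,
                            scorer = NULL, presence = NULL,
                            keep = character()) {
  X <- as.data.frame(samples)
  vars <- names(X)
  if (is.null(scorer)) {
    scorer <- if (!is.null(presence)) maxentGainScorer(presence, X)
              else function(variable) 0
  }
  scores <- vapply(vars, scorer, numeric(1))
  names(scores) <- vars
  corMat <- pearsonMatrix(X)
  clusters <- .corClusters(corMat, rThreshold)
  droppedVar <- character()
  droppedWhy <- character()
  kept <- character()
  for (cl in clusters) {
    if (length(cl) == 1L) {
      kept <- c(kept, cl)
      next
    }
    forced <- intersect(cl, keep)
    best <- if (length(forced)) forced[1L]
            else cl[which.max(scores[cl])]   # ties: earliest in order
    kept <- c(kept, best)
    rest <- setdiff(cl, best)
    droppedVar <- c(droppedVar, rest)
    droppedWhy <- c(droppedWhy, rep("pairwise", length(rest)))
  }
  kept <- vars[vars %in% kept]               # canonical order
  vifAll <- vifScores(X)
  repeat {
    if (length(kept) < 2L) break
    v <- vifScores(X[, kept, drop = FALSE])
    over <- names(v)[v > vifThreshold]
    over <- setdiff(over, keep)
    if (!length(over)) break
    worst <- over[order(scores[over],
                        -match(over, vars))][1L]  # lowest score; ties: latest
    kept <- setdiff(kept, worst)
    droppedVar <- c(droppedVar, worst)
    droppedWhy <- c(droppedWhy, "vif")
  }
  if (!length(kept)) stop("selection dropped every candidate variable")
  vifKept <- if (length(kept) >= 2L) vifScores(X[, kept, drop = FALSE])
             else stats::setNames(1, kept)
  list(
    correlation = corMat,
    vif = vifAll,
    vifKept = vifKept,
    clusters = clusters,
    kept = kept,
    dropped = data.frame(variable = droppedVar, reason = droppedWhy,
                         stringsAsFactors = FALSE),
    scores = scores,
    thresholds = c(r = rThreshold, vif = vifThreshold)
  )
}
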