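#' @include maxent-features.R rng.R
NULL

# stable log(sum(w * exp(x)))
.logSumExpW <- function(x, w) {
  m <- max(x)
  m + log(sum(w * exp(x - m)))
}

# smooth part of the penalized objective and its gradient
# f(lambda) = -mean_p(lambda.Fp) + log sum_b w_b exp(lambda.Fb) - log sum_b w_b
.maxentSmooth <- function(lambda, Fp, Fb, w, logSumW) {
  etaB <- drop(Fb %*% lambda)
  lZ <- .logSumExpW(etaB, w)
  val <- -mean(drop(Fp %*% lambda)) + lZ - logSumW
  q <- w * exp(etaB - lZ)          # Gibbs weights, sum to 1
  grad <- -colMeans(Fp) + drop(crossprod(Fb, q))
  list(value = val, grad = grad, logZ = lZ, q = q)
}

.softThreshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# FISTA (accelerated proximal gradient with backtracking and adaptive
# restart) for the L1-penalized maxent objective
.fitMaxentSolver <- function(Fp, Fb, w, rho, tol = 1e-8, maxIter = 5000L) {
  nf <- ncol(Fb)
  logSumW <- log(sum(w))
  lambda <- numeric(nf)
  yv <- lambda
  tk <- 1
  L <- 1
  sm <- .maxentSmooth(lambda, Fp, Fb, w, logSumW)
  obj <- sm$value + sum(rho * abs(lambda))
  for (it in seq_len(maxIter)) {
    smY <- .maxentSmooth(yv, Fp, Fb, w, logSumW)
    repeat {
      cand <- .softThreshold(yv - smY$grad / L, rho / L)
      dv <- cand - yv
      smC <- .maxentSmooth(cand, Fp, Fb, w, logSumW)
      if (smC$value <= smY$value + sum(smY$grad * dv) +
            L / 2 * sum(dv^2) + 1e-14) break
      L <- L * 2
    }
    newObj <- smC$value + sum(rho * abs(cand))
    if (newObj > obj + 1e-14) {        # restart momentum
      yv <- lambda
      tk <- 1
      L <- L / 2
      next
    }
    tNew <- (1 + sqrt(1 + 4 * tk^2)) / 2
    yv <- cand + (tk - 1) / tNew * (cand - lambda)
    converged <- abs(obj - newObj) <= tol * max(1, abs(newObj))
    lambda <- cand
    obj <- newObj
    tk <- tNew
    L <- max(L / 1.5, 1e-6)
    if (converged && it > 3) break
  }
  sm <- .maxentSmooth(lambda, Fp, Fb, w, logSumW)
  list(lambda = lambda, logZ = sm$logZ, q = sm$q,
       objective = sm$value + sum(rho * abs(lambda)), iterations = it)
}

#' Fit a maximum-entropy presence/background model
#'
#' Maximizes the L1-penalized presence log-likelihood of the Gibbs density
#' `q(x) = w(x) exp(lambda . f(x)) / Z` over the background sample, with
#' per-feature penalty `rho_j = beta * s_j / sqrt(m)` (`s_j` the feature sd
#' over the background, `m` the presence count). Features are linear +
#' quadratic in each continuous covariate, one-hot for categoricals; no
#' threshold or hinge features. Background weights act as the base measure
#' in the partition function; presence likelihood terms are never weighted,
#' so an all-ones weight vector reproduces the unweighted fit exactly.
#'
#' @param presence data.frame of presence covariates.
#' @param background data.frame of background covariates (same columns).
#' @param weights optional nonnegative background weights (default all 1).
#' @param beta global regularization multiplier (default 3).
#' @param transform output transform: `"cloglog"` (default), `"logistic"`
#'   or `"raw"`.
#' @param categorical named list of categorical levels (see
#'   [buildFeatureMap()]).
#' @param tol relative objective convergence tolerance.
#' @param maxIter iteration cap for the solver.
#' @param meta optional list of metadata stored with the model.
#' @return a [MaxentModel-class]
#' @examples
#' bg <- data.frame(t1 = rnorm(200))
#' pr <- data.frame(t1 = rnorm(30, mean = 1))
#' m <- maxentFit(pr, bg, beta = 1)
#' mean(maxentPredict(m, pr)) > mean(maxentPredict(m, bg))
#' @export
maxentFit <- function(presence, background, weights = NULL, beta = 3,
                      transform = "cloglog", categorical = list(),
                      tol = 1e-8, maxIter = 5000L, meta = list()) {
  presence <- as.data.frame(presence)
  background <- as.data.frame(background)
  m <- nrow(presence)
  if (m < 2) stop("at least 2 presence records are required")
  if (m < 10)
    warning("fewer than 10 presences; the fit may be unstable")
  if (nrow(background) < m)
    warning("background smaller than the presence set")
  if (is.null(weights)) weights <- rep(1, nrow(background))
  if (length(weights) != nrow(background))
    stop("'weights' must have one entry per background point")
  if (any(weights < 0)) stop("background weights must be nonnegative")
  if (all(weights == 0)) stop("all background weights are zero")
  map <- buildFeatureMap(background, categorical)
  presence <- presence[, names(map$variables), drop = FALSE]
  Fb <- expandFeatures(map, background)
  Fp <- expandFeatures(map, presence)
  # degenerate expanded features get zero sd -> zero penalty scale would
  # let them blow up; drop them instead (constant features carry no signal)
  keep <- map$featureSd > 1e-12
  rho <- beta * map$featureSd[keep] / sqrt(m)
  sol <- .fitMaxentSolver(Fp[, keep, drop = FALSE],
                          Fb[, keep, drop = FALSE],
                          weights, rho, tol = tol, maxIter = maxIter)
  if (max(abs(sol$lambda)) > 50)
    warning("very large coefficients: presence features may be separable ",
            "from the background (objective near-unbounded); consider a ",
            "larger beta or more data")
  lambda <- numeric(ncol(Fb))
  names(lambda) <- colnames(Fb)
  lambda[keep] <- sol$lambda
  rhoFull <- numeric(ncol(Fb))
  names(rhoFull) <- colnames(Fb)
  rhoFull[keep] <- rho
  # entropy of the fitted density over the training background (weighted
  # point masses), used by the cloglog / logistic output transforms
  q <- sol$q
  H <- -sum(q[q > 0] * log(q[q > 0]))
  meta$nPresence <- m
  meta$nBackground <- nrow(background)
  meta$iterations <- sol$iterations
  meta$objective <- sol$objective
  new("MaxentModel", coef = lambda, beta = beta, regScale = rhoFull,
      featureMap = map, logZ = sol$logZ, entropy = H,
      transform = transform, meta = meta)
}

#' Predict suitability from a fitted model
#'
#' Computes the raw relative density `exp(lambda . f(x) - logZ)` (clamped
#' feature expansion) and applies the model's output transform: cloglog
#' `1 - exp(-exp(H) * raw)` or logistic `exp(H) raw / (1 + exp(H) raw)`,
#' with `H` the training-background entropy; both live in (0, 1).
#'
#' @param model a [MaxentModel-class]
#' @param newdata data.frame of covariates, or a named list of
#'   [GridRaster-class] layers (one per model variable).
#' @param transform optional override of the model's output transform.
#' @return numeric vector, or a [GridRaster-class] when `newdata` is a
#'   raster stack.
#' @export
maxentPredict <- function(model, newdata, transform = NULL) {
  if (is.null(transform)) transform <- model@transform
  if (is.list(newdata) && !is.data.frame(newdata) &&
      all(vapply(newdata, is, logical(1), "GridRaster"))) {
    ref <- newdata[[1L]]
    df <- as.data.frame(lapply(newdata, function(r) c(r@values)))
    ok <- stats::complete.cases(df)
    out <- rep(NA_real_, nrow(df))
    if (any(ok))
      out[ok] <- maxentPredict(model, df[ok, , drop = FALSE], transform)
    return(gridRaster(matrix(out, nrow(ref@values), ncol(ref@values)),
                      ref@cellKm, ref@origin, "suitability"))
  }
  F <- expandFeatures(model@featureMap, as.data.frame(newdata))
  raw <- exp(drop(F %*% model@coef) - model@logZ)
  switch(transform,
    raw = raw,
    cloglog = 1 - exp(-exp(model@entropy) * raw),
    logistic = {
      er <- exp(model@entropy) * raw
      er / (1 + er)
    },
    stop("unknown transform '", transform, "'"))
}

#' @describeIn maxentPredict S4 `predict` method.
#' @param object a [MaxentModel-class]
#' @param ... passed to `maxentPredict`
#' @export
setMethod("predict", "MaxentModel", function(object, ...) {
  maxentPredict(object, ...)
})

#' Replicate-averaged fit with held-out evaluation
#'
#' Draws `nReplicates` independent 70/30 presence splits (the background is
#' shared across replicates), fits each training subset, and evaluates each
#' replicate on its held-out presences against the background with AUC and
#' the continuous Boyce index. The final prediction is the arithmetic mean
#' of the replicate predictions.
#'
#' @inheritParams maxentFit
#' @param nReplicates number of replicate splits (default 10).
#' @param trainFraction presence fraction used for calibration
#'   (default 0.7).
#' @param seed integer seed governing the splits.
#' @return a [MaxentEnsemble-class]
#' @export
replicateFit <- function(presence, background, weights = NULL,
                         nReplicates = 10, trainFraction = 0.7, seed = 1,
                         beta = 3, transform = "cloglog",
                         categorical = list(), tol = 1e-8,
                         maxIter = 5000L) {
  presence <- as.data.frame(presence)
  m <- nrow(presence)
  if (trainFraction < 1 && m < 4)
    stop("too few presences (< 4) to split for evaluation")
  stopifnot(nReplicates >= 1)
  models <- vector("list", nReplicates)
  ev <- vector("list", nReplicates)
  for (i in seq_len(nReplicates)) {
    idx <- withSubstream(seed, "split", index = i, {
      if (trainFraction >= 1) seq_len(m)
      else sample.int(m, max(2L, floor(trainFraction * m)))
    })
    fitMeta <- list(replicate = i, seed = seed)
    models[[i]] <- maxentFit(presence[idx, , drop = FALSE], background,
                             weights, beta, transform, categorical,
                             tol, maxIter, meta = fitMeta)
    if (trainFraction < 1) {
      hold <- presence[-idx, , drop = FALSE]
      ps <- maxentPredict(models[[i]], hold)
      bs <- maxentPredict(models[[i]], background)
      cbi <- tryCatch(continuousBoyceIndex(ps, bs)$cbi,
                      error = function(e) NA_real_)
      ev[[i]] <- data.frame(replicate = i, auc = aucScore(ps, bs),
                            cbi = cbi, nPresenceEval = nrow(hold),
                            nBackgroundEval = nrow(background))
    }
  }
  evaluation <- if (length(ev) && !is.null(ev[[1L]])) do.call(rbind, ev)
                else data.frame()
  new("MaxentEnsemble", models = models, evaluation = evaluation,
      meta = list(seed = seed, trainFraction = trainFraction,
                  nReplicates = nReplicates, beta = beta))
}

#' Predict with a replicate ensemble
#'
#' Arithmetic mean of the replicate predictions on the transform scale;
#' raster stacks are averaged cell-wise.
#'
#' @param ensemble a [MaxentEnsemble-class]
#' @param newdata covariate data.frame or named raster list.
#' @param transform optional transform override.
#' @return numeric vector or [GridRaster-class].
#' @export
ensemblePredict <- function(ensemble, newdata, transform = NULL) {
  preds <- lapply(ensemble@models, maxentPredict, newdata = newdata,
                  transform = transform)
  if (is(preds[[1L]], "GridRaster")) {
    vals <- Reduce(`+`, lapply(preds, rasterValues)) / length(preds)
    r <- preds[[1L]]
    r@values <- vals
    return(r)
  }
  Reduce(`+`, preds) / length(preds)
}

#' @describeIn ensemblePredict S4 `predict` method.
#' @param object a [MaxentEnsemble-class]
#' @param ... passed to `ensemblePredict`
#' @export
setMethod("predict", "MaxentEnsemble", function(object, ...) {
  ensemblePredict(object, ...)
})

#' Training gain scorer for univariate screening
#'
#' Returns a function scoring a single variable by the training gain of a
#' one-variable maxent fit: the fitted mean presence log-density relative
#' to the null (uniform) model. Used as the default relative-contribution
#' score when collapsing collinear variable clusters.
#'
#' @param presence,background covariate data.frames.
#' @param beta regularization multiplier for the screening fits.
#' @return `function(variable) -> numeric score`.
#' @export
maxentGainScorer <- function(presence, background, beta = 3) {
  force(presence); force(background); force(beta)
  function(variable) {
    p1 <- presence[, variable, drop = FALSE]
    b1 <- background[, variable, drop = FALSE]
    fit <- suppressWarnings(
      maxentFit(p1, b1, beta = beta, tol = 1e-6, maxIter = 1000L))
    F <- expandFeatures(fit@featureMap, p1)
    mean(drop(F %*% fit@coef)) - fit@logZ + log(nrow(b1))
  }
}
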