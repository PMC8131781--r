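test_that("null data shrinks every coefficient toward zero", {
  set.seed(20)
  bg <- data.frame(a = rnorm(10000), b = runif(10000))
  pres <- bg[sample.int(10000, 500), ]
  m <- maxentFit(pres, bg, beta = 3)
  pred <- maxentPredict(m, bg)
  expect_lt(sd(pred), 0.02)
})

test_that("a presence shift yields a positive linear coefficient", {
  d <- toyPresenceBackground(seed = 21)
  m <- maxentFit(d$presence, d$background, beta = 1)
  expect_gt(m@coef[["a"]], 0)
})

test_that("the solver matches an independent coarse optimizer", {
  set.seed(42)
  bg <- data.frame(a = rnorm(30), b = runif(30))
  pres <- data.frame(a = rnorm(12, 1.5, 0.5), b = runif(12)^2)
  m <- suppressWarnings(maxentFit(pres, bg, beta = 0.5))
  Fb <- expandFeatures(m@featureMap, bg)
  Fp <- expandFeatures(m@featureMap, pres)
  rho <- 0.5 * m@featureMap$featureSd / sqrt(nrow(pres))
  lse <- function(x) { mx <- max(x); mx + log(sum(exp(x - mx))) }
  obj <- function(l) -mean(Fp %*% l) + lse(Fb %*% l) -
    log(nrow(bg)) + sum(rho * abs(l))
  o <- optim(rep(0, 4), obj, method = "Nelder-Mead",
             control = list(maxit = 50000, reltol = 1e-15))
  for (k in 1:5)
    o <- optim(o$par, obj, method = "Nelder-Mead",
               control = list(maxit = 50000, reltol = 1e-15))
  expect_lt(max(abs(m@coef - o$par)), 1e-3)
  # convexity audit: no random perturbation improves the objective
  best <- obj(m@coef)
  set.seed(43)
  for (k in 1:100)
    expect_gte(obj(m@coef + rnorm(4, 0, 0.05)), best - 1e-10)
})

test_that("the weighted Gibbs density normalizes over the background", {
  d <- toyPresenceBackground(seed = 22, nP = 80, nB = 1000)
  w <- runif(1000, 0.2, 1)
  m <- maxentFit(d$presence, d$background, weights = w, beta = 1)
  Fb <- expandFeatures(m@featureMap, d$background)
  total <- sum(w * exp(drop(Fb %*% m@coef) - m@logZ))
  expect_equal(total, 1, tolerance = 1e-8)
})

test_that("stronger regularization never grows the L1 norm", {
  d <- toyPresenceBackground(seed = 23, nP = 100, nB = 1500)
  norms <- vapply(c(0.5, 1, 3, 10), function(b)
    sum(abs(maxentFit(d$presence, d$background, beta = b)@coef)),
    numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("unit weights reproduce the unweighted fit exactly", {
  d <- toyPresenceBackground(seed = 24, nP = 60, nB = 800)
  m1 <- maxentFit(d$presence, d$background, beta = 2)
  m2 <- maxentFit(d$presence, d$background,
                  weights = rep(1, 800), beta = 2)
  expect_identical(m1@coef, m2@coef)
  expect_identical(m1@logZ, m2@logZ)
})

test_that("degenerate inputs are rejected or dropped as documented", {
  d <- toyPresenceBackground(seed = 25, nP = 40, nB = 500)
  bad <- d$presence; bad$a[1] <- Inf
  expect_error(maxentFit(bad, d$background), "non-finite")
  expect_error(maxentFit(d$presence, d$background,
                         weights = rep(0, 500)), "zero")
  # constant covariate is dropped, not fatal
  d$background$c <- 1; d$presence$c <- 1
  m <- maxentFit(d$presence, d$background)
  expect_false("c" %in% names(m@featureMap$variables))
  expect_true("c" %in% m@featureMap$dropped)
})

test_that("prediction transforms and clamping behave as specified", {
  d <- toyPresenceBackground(seed = 26)
  m <- maxentFit(d$presence, d$background, beta = 1)
  # all-zero model predicts a constant
  m0 <- m; m0@coef[] <- 0
  p0 <- maxentPredict(m0, d$background)
  expect_lt(diff(range(p0)), 1e-12)
  # monotone in a variable whose only effect is a positive linear term
  mLin <- m
  mLin@coef[] <- 0
  mLin@coef["a"] <- 1
  sweep <- data.frame(a = seq(min(d$background$a), max(d$background$a),
                              length.out = 50), b = 0)
  ps <- maxentPredict(mLin, sweep)
  expect_true(all(diff(ps) > 0))
  # duplicated rows predict identically; missing variable errors by name
  expect_identical(maxentPredict(m, d$presence[c(1, 1), ]),
                   rep(maxentPredict(m, d$presence[1, ]), 2))
  expect_error(maxentPredict(m, d$presence["a"]), "b")
  # beyond-range covariates are clamped to the training bounds
  hi <- data.frame(a = max(d$background$a) + 10, b = 0)
  atMax <- data.frame(a = max(d$background$a), b = 0)
  expect_equal(maxentPredict(m, hi), maxentPredict(m, atMax))
  # logistic and cloglog both stay inside (0, 1)
  for (tr in c("cloglog", "logistic")) {
    p <- maxentPredict(m, d$background, transform = tr)
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("replicate averaging reduces to the single fit in the limit", {
  d <- toyPresenceBackground(seed = 27, nP = 60, nB = 800)
  ens <- replicateFit(d$presence, d$background, nReplicates = 1,
                      trainFraction = 1, seed = 5, beta = 2)
  single <- maxentFit(d$presence, d$background, beta = 2)
  expect_identical(ens@models[[1]]@coef, single@coef)
  expect_identical(ensemblePredict(ens, d$background),
                   maxentPredict(single, d$background))
})

test_that("replicate ensembles are seed-reproducible and bounded", {
  d <- toyPresenceBackground(seed = 28, nP = 80, nB = 1000)
  e1 <- replicateFit(d$presence, d$background, nReplicates = 4, seed = 7)
  e2 <- replicateFit(d$presence, d$background, nReplicates = 4, seed = 7)
  expect_identical(lapply(e1@models, function(m) m@coef),
                   lapply(e2@models, function(m) m@coef))
  # averaged prediction is bounded by the replicate envelope pointwise
  preds <- vapply(e1@models, maxentPredict, numeric(1000),
                  newdata = d$background)
  avg <- ensemblePredict(e1, d$background)
  expect_true(all(avg >= apply(preds, 1, min) - 1e-12))
  expect_true(all(avg <= apply(preds, 1, max) + 1e-12))
  # held-out evaluation recorded per replicate
  expect_equal(nrow(e1@evaluation), 4)
  expect_error(replicateFit(d$presence[1:3, ], d$background, seed = 1),
               "few")
})

test_that("variable contributions isolate the informative covariate", {
  set.seed(29)
  hits <- 0
  for (k in 1:20) {
    bg <- data.frame(a = rnorm(600), b = rnorm(600))
    pres <- data.frame(a = rnorm(60, 1.3, 0.6), b = rnorm(60))
    m <- maxentFit(pres, bg, beta = 1)
    v <- variableContribution(m, pres, bg, nPermutations = 5, seed = k)
    if (v[["a"]] > v[["b"]]) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("single-variable contributions are total", {
  set.seed(30)
  bg <- data.frame(a = rnorm(500))
  pres <- data.frame(a = rnorm(50, 1))
  m <- maxentFit(pres, bg, beta = 1)
  v <- variableContribution(m, pres, bg, seed = 1)
  expect_equal(unname(v), 100)
  expect_equal(sum(v), 100)
})

test_that("response curves reflect the fitted feature shape", {
  d <- toyPresenceBackground(seed = 31)
  m <- maxentFit(d$presence, d$background, beta = 1)
  # flat for an all-zero model
  m0 <- m; m0@coef[] <- 0
  rc0 <- responseCurve(m0, "a")
  expect_lt(diff(range(rc0$suitability)), 1e-12)
  # monotone for a positive linear model
  mLin <- m; mLin@coef[] <- 0; mLin@coef["a"] <- 0.8
  expect_true(all(diff(responseCurve(mLin, "a")$suitability) > 0))
  # pure negative quadratic peaks at the background mean
  mQ <- m; mQ@coef[] <- 0; mQ@coef["a^2"] <- -1
  rcQ <- responseCurve(mQ, "a", nPoints = 201)
  peak <- rcQ$value[which.max(rcQ$suitability)]
  expect_lt(abs(peak - mean(d$background$a)),
            diff(range(d$background$a)) / 100)
  expect_error(responseCurve(m, "zz"), "not a model variable")
})
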