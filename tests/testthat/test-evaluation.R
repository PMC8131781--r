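test_that("AUC matches exact pair counting, including ties", {
  expect_equal(aucScore(c(0.9, 0.8), c(0.2, 0.1)), 1)
  expect_equal(aucScore(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  expect_equal(aucScore(c(0.8, 0.3), c(0.5, 0.1)), 0.75)
  set.seed(40)
  for (k in 1:25) {
    p <- sample(seq(0, 1, 0.05), sample(2:8, 1), replace = TRUE)
    b <- sample(seq(0, 1, 0.05), sample(2:10, 1), replace = TRUE)
    expect_equal(aucScore(p, b), bruteAUC(p, b), tolerance = 1e-12)
  }
  expect_error(aucScore(numeric(0), 1), "non-empty")
})

test_that("AUC is invariant under monotone transforms and flips on reversal", {
  set.seed(41)
  p <- runif(40); b <- runif(60)
  a <- aucScore(p, b)
  expect_equal(aucScore(qlogis(p), qlogis(b)), a)
  expect_equal(aucScore(exp(5 * p), exp(5 * b)), a)
  expect_equal(aucScore(-p, -b), 1 - a)
})

test_that("the Boyce index hits +-1 on monotone constructions", {
  land <- seq(0, 1, length.out = 5000)
  top <- continuousBoyceIndex(seq(0.9, 1, length.out = 500), land)
  expect_equal(top$cbi, 1)
  bottom <- continuousBoyceIndex(seq(0, 0.1, length.out = 500), land)
  expect_equal(bottom$cbi, -1)
  # P/E curve is reported over the windows
  expect_true(all(c("center", "P", "E", "PE") %in% names(top$curve)))
  expect_error(continuousBoyceIndex(rep(0.5, 10), rep(0.5, 10)),
               "constant")
})

test_that("the Boyce index stays near zero for random predictions", {
  set.seed(42)
  ok <- 0
  for (k in 1:50) {
    land <- runif(4000)
    pres <- sample(land, 1000, replace = TRUE)
    if (abs(continuousBoyceIndex(pres, land)$cbi) < 0.3) ok <- ok + 1
  }
  expect_gte(ok, 45)
})

test_that("the Boyce index is invariant under affine score transforms", {
  set.seed(43)
  land <- runif(3000)
  pres <- runif(400)^0.5
  a <- continuousBoyceIndex(pres, land)$cbi
  # power-of-two scaling keeps every window boundary exactly aligned
  expect_identical(a, continuousBoyceIndex(4 * pres, 4 * land)$cbi)
  # a general affine map can flip single points across window boundaries
  # through floating-point rounding; the index moves at most marginally
  b <- continuousBoyceIndex(3 * pres + 2, 3 * land + 2)$cbi
  expect_equal(a, b, tolerance = 0.01)
})

test_that("model evaluation reports both metrics and flags degeneracy", {
  d <- toyPresenceBackground(seed = 44, nP = 200, nB = 3000)
  m <- maxentFit(d$presence, d$background, beta = 1)
  rep <- evaluateModel(m, d$presence, d$background)
  expect_s3_class(rep, "evaluationReport")
  expect_gt(rep$auc, 0.5)
  expect_false(rep$degenerate)
  expect_equal(rep$region, "calibration")
  # constant model: AUC one half, CBI undefined, flagged
  m0 <- m; m0@coef[] <- 0
  rep0 <- evaluateModel(m0, d$presence, d$background)
  expect_equal(rep0$auc, 0.5)
  expect_true(is.na(rep0$cbi))
  expect_true(rep0$degenerate)
})

test_that("a faithful model scores well on its own equilibrium sample", {
  scen <- twoRegionScenario(seed = 45, nRow = 80, nCol = 80)
  occ <- sampleOccurrencesEquilibrium(scen$truth, scen$native, 400,
                                      seed = 1,
                                      suitability = scen$suitNative)
  sPres <- extractAt(scen$suitNative, occ$x, occ$y)
  sLand <- c(rasterValues(scen$suitNative))
  expect_gt(aucScore(sPres, sLand), 0.8)
  expect_gt(continuousBoyceIndex(sPres, sLand)$cbi, 0.5)
})

test_that("training evaluation is optimistic relative to held-out, on average", {
  set.seed(46)
  gaps <- numeric(20)
  for (k in 1:20) {
    bg <- data.frame(a = rnorm(800), b = rnorm(800))
    pres <- data.frame(a = rnorm(80, 1, 0.7), b = rnorm(80))
    idx <- sample(80, 56)
    m <- maxentFit(pres[idx, ], bg, beta = 1)
    gaps[k] <- aucScore(maxentPredict(m, pres[idx, ]),
                        maxentPredict(m, bg)) -
      aucScore(maxentPredict(m, pres[-idx, ]), maxentPredict(m, bg))
  }
  expect_gt(mean(gaps), 0)
})

test_that("transfer reports tag the region and match evaluation on identity", {
  d <- toyPresenceBackground(seed = 47, nP = 100, nB = 1500)
  m <- maxentFit(d$presence, d$background, beta = 1)
  cal <- evaluateModel(m, d$presence, d$background)
  tr <- transferReport(m, d$presence, d$background)
  expect_equal(tr$region, "transfer")
  expect_equal(tr$auc, cal$auc)
  expect_equal(tr$cbi, cal$cbi)
})
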