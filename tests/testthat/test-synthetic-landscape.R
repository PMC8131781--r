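test_that("climate generator controls pairwise correlation", {
  cl <- generateClimate(300, 300, 1, diag(2), autocorrRangeKm = 5, seed = 4)
  r <- cor(c(rasterValues(cl[[1]])), c(rasterValues(cl[[2]])))
  expect_lt(abs(r), 0.05)
  # requested correlation is reproduced
  tc <- matrix(c(1, 0.6, 0.6, 1), 2)
  cl2 <- generateClimate(200, 200, 1, tc, autocorrRangeKm = 5, seed = 4)
  r2 <- cor(c(rasterValues(cl2[[1]])), c(rasterValues(cl2[[2]])))
  expect_lt(abs(r2 - 0.6), 0.05)
})

test_that("degenerate unit correlation gives affinely identical layers", {
  tc <- matrix(1, 2, 2)
  cl <- generateClimate(100, 100, 1, tc, autocorrRangeKm = 3, seed = 2)
  r <- cor(c(rasterValues(cl[[1]])), c(rasterValues(cl[[2]])))
  expect_gt(abs(r), 0.999)
})

test_that("non-positive-definite target matrix is rejected", {
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(generateClimate(50, 50, 1, bad, 3, seed = 1),
               "positive semi-definite")
})

test_that("generators are bit-identical under one seed", {
  a <- generateClimate(60, 60, 1, diag(3), 4, seed = 11)
  b <- generateClimate(60, 60, 1, diag(3), 4, seed = 11)
  expect_identical(lapply(a, rasterValues), lapply(b, rasterValues))
  h1 <- generateHabitat(60, 60, 1, 4, 0.3, 2, seed = 5)
  h2 <- generateHabitat(60, 60, 1, 4, 0.3, 2, seed = 5)
  expect_identical(rasterValues(h1$habitat), rasterValues(h2$habitat))
  expect_identical(rasterValues(h1$host), rasterValues(h2$host))
})

test_that("host prevalence is matched and habitat clusters with range", {
  h <- generateHabitat(300, 300, 1, 5, 0.2, 3, seed = 9)
  frac <- mean(rasterValues(h$host))
  expect_gt(frac, 0.17)
  expect_lt(frac, 0.23)
  # degenerate full-host case
  h1 <- generateHabitat(40, 40, 1, 3, 1, 2, seed = 1)
  expect_true(all(rasterValues(h1$host) == 1))
  # dem smooth and nonnegative
  expect_true(all(rasterValues(h$dem) >= 0))
  # clustering: iid classes fragment far more than clustered ones
  iid <- generateHabitat(80, 80, 1, 4, 0.5, 0, seed = 3)
  clus <- generateHabitat(80, 80, 1, 4, 0.5, 10, seed = 3)
  pIid <- brutePatchCount(rasterValues(iid$habitat))
  pClus <- brutePatchCount(rasterValues(clus$habitat))
  expect_gt(pIid, pClus)
  # iid patch count is on the order of cells * (1 - 1/n_classes)
  expect_gt(pIid, 0.5 * 80 * 80 * (1 - 1 / 4))
})

test_that("true suitability reproduces its closed form", {
  # flat niche: constant one half
  cl <- list(v = constRaster(0.3, 4, 4))
  tr <- virtualSpeciesTruth(0, c(v = 0), c(v = 0))
  s <- trueSuitability(tr, cl, center = 0, scale = 1)
  expect_equal(rasterValues(s), matrix(0.5, 4, 4))
  # single quadratic variable: max one half at z = 0, symmetric decay
  z <- matrix(seq(-2, 2, length.out = 5), 1)
  cl2 <- list(v = gridRaster(z))
  tr2 <- virtualSpeciesTruth(0, c(v = 0), c(v = -1))
  s2 <- c(rasterValues(trueSuitability(tr2, cl2, center = 0, scale = 1)))
  expect_equal(max(s2), 0.5)
  expect_equal(which.max(s2), 3L)
  expect_equal(s2[1], s2[5])
  # hand-evaluated cell: plogis(1 + 1 - 1) = plogis(1)
  cl3 <- list(v1 = constRaster(1, 1, 1), v2 = constRaster(-1, 1, 1))
  tr3 <- virtualSpeciesTruth(1, c(v1 = 1, v2 = 0), c(v1 = -1, v2 = 0))
  s3 <- c(rasterValues(trueSuitability(tr3, cl3, center = 0, scale = 1)))
  expect_equal(s3, plogis(1), tolerance = 1e-12)
  # missing layer named in the error
  expect_error(trueSuitability(tr3, cl3["v1"]), "v2")
})

test_that("equilibrium sampling concentrates on suitable host cells", {
  scen <- twoRegionScenario(seed = 21, nRow = 80, nCol = 80)
  occ <- sampleOccurrencesEquilibrium(scen$truth, scen$native, 2000,
                                      seed = 5,
                                      suitability = scen$suitNative)
  sAtOcc <- extractAt(scen$suitNative, occ$x, occ$y)
  expect_gt(mean(sAtOcc), mean(rasterValues(scen$suitNative)))
  # no duplicate cell-year records under the default thinning
  expect_silent(validateOccurrences(occ))
})

test_that("degenerate equilibrium cases behave as documented", {
  # all mass in one cell: every unthinned record lands there
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  land <- landscapeBundle(list(v = gridRaster(m)), constRaster(1),
                          constRaster(1), constRaster(0, 5, 5))
  # niche flat, host-independent; weight comes from suitability raster
  tr <- virtualSpeciesTruth(0, c(v = 0), c(v = 0), hostDependent = FALSE)
  occ <- sampleOccurrencesEquilibrium(tr, land, 50, seed = 1, thin = FALSE,
                                      suitability = gridRaster(m))
  expect_equal(nrow(occ), 50)
  expect_true(all(occ$x == 2.5 & occ$y == 2.5))
  # host-dependent species with no host anywhere: empty support
  land0 <- landscapeBundle(list(v = gridRaster(m)), constRaster(0),
                           constRaster(1), constRaster(0, 5, 5))
  trH <- virtualSpeciesTruth(0, c(v = 0), c(v = 0), hostDependent = TRUE)
  expect_error(sampleOccurrencesEquilibrium(trH, land0, 5, seed = 1),
               "positive sampling weight")
})

test_that("invasion respects the dispersal radius and is monotone", {
  rs <- regionalScenario(seed = 31, nRow = 100, nCol = 100)
  occ <- rbind(rs$occPrev, rs$occCurrent)
  yrs <- sort(unique(occ$year))
  expect_gt(length(yrs), 2)
  for (i in 2:length(yrs)) {
    new <- occ[occ$year == yrs[i], , drop = FALSE]
    old <- occ[occ$year < yrs[i], , drop = FALSE]
    jump <- vapply(seq_len(nrow(new)), function(j)
      min(sqrt((old$x - new$x[j])^2 + (old$y - new$y[j])^2)), numeric(1))
    expect_lte(max(jump), rs$truth@dispersalRadiusKm + 1e-9)
  }
  # occupied cells never repeat: one record per colonised cell
  expect_false(anyDuplicated(occ[, c("x", "y")]) > 0)
})

test_that("zero dispersal confines the invasion to the introduction cell", {
  m <- matrix(0.8, 10, 10)
  land <- landscapeBundle(list(v = gridRaster(m)), constRaster(1, 10, 10),
                          constRaster(1, 10, 10), constRaster(0, 10, 10))
  tr <- virtualSpeciesTruth(1, c(v = 0), c(v = 0), hostDependent = FALSE,
                            dispersalRadiusKm = 0)
  occ <- simulateInvasion(tr, land, data.frame(x = 4.5, y = 4.5), 4, 10,
                          seed = 2, suitability = gridRaster(m))
  expect_true(all(occ$x == 4.5 & occ$y == 4.5))
})

test_that("dispersal beyond the diagonal reduces to full-support sampling", {
  m <- matrix(0.8, 12, 12)
  land <- landscapeBundle(list(v = gridRaster(m)), constRaster(1, 12, 12),
                          constRaster(1, 12, 12), constRaster(0, 12, 12))
  tr <- virtualSpeciesTruth(1, c(v = 0), c(v = 0), hostDependent = FALSE,
                            dispersalRadiusKm = 50)
  occ <- simulateInvasion(tr, land, data.frame(x = 0.5, y = 0.5), 2, 200,
                          seed = 2, suitability = gridRaster(m))
  # year 2 colonises every remaining cell: support equals the whole grid
  expect_equal(nrow(occ), 144)
})

test_that("invasion-front records realize a truncated climate niche", {
  for (sd in c(1, 2)) {
    scen <- twoRegionScenario(seed = sd)
    nat <- extractAt(scen$native@climate$clim1,
                     scen$nativeOcc$x, scen$nativeOcc$y)
    inv <- extractAt(scen$invaded@climate$clim1,
                     scen$invadedOcc$x, scen$invadedOcc$y)
    # central 95% of the realized niche: the dispersal-limited front is
    # truncated on the optimum side and realizes a narrower breadth than
    # the equilibrium sample (the front may touch marginal low-end cells
    # near the introduction, so only the upper tail and the breadth are
    # informative about truncation)
    qn <- quantile(nat, c(0.025, 0.975))
    qi <- quantile(inv, c(0.025, 0.975))
    expect_lt(qi[[2]], qn[[2]])
    expect_lt(diff(qi), diff(qn))
  }
})

test_that("severity fraction rises with true suitability", {
  scen <- twoRegionScenario(seed = 8)
  occ <- sampleOccurrencesEquilibrium(scen$truth, scen$native, 3000,
                                      seed = 3,
                                      suitability = scen$suitNative)
  s <- extractAt(scen$suitNative, occ$x, occ$y)
  q <- cut(s, breaks = quantile(s, 0:4 / 4), include.lowest = TRUE)
  frac <- tapply(occ$severity >= 3, q, mean)
  expect_true(all(diff(frac) >= 0))
})
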