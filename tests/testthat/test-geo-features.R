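test_that("focal percentage handles constant and degenerate inputs", {
  ones <- constRaster(1, 9, 9)
  expect_true(all(rasterValues(focalPercentage(ones, 3)) == 100))
  zeros <- constRaster(0, 9, 9)
  expect_true(all(rasterValues(focalPercentage(zeros, 3)) == 0))
  # radius below the cell size reduces to the input times 100
  m <- matrix(runif(25), 5)
  r <- gridRaster(m, cellKm = 1)
  expect_equal(rasterValues(focalPercentage(r, 0.3)), 100 * m)
})

test_that("focal statistics match the exhaustive window oracle", {
  set.seed(5)
  m <- matrix(rbinom(21 * 21, 1, 0.3), 21, 21)
  m[sample(441, 30)] <- NA          # masked cells excluded on both sides
  r <- gridRaster(m, cellKm = 1)
  for (rad in c(1, 2.5)) {
    got <- rasterValues(focalPercentage(r, rad))
    want <- 100 * bruteFocalMean(m, rad, 1)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # single positive cell spreads 100/W over the window
  m2 <- matrix(0, 21, 21); m2[11, 11] <- 1
  g2 <- rasterValues(focalPercentage(gridRaster(m2), 2))
  W <- sum(outer((-2):2, (-2):2, function(a, b) a^2 + b^2) <= 4)
  expect_equal(g2[11, 11], 100 / W)
  # focal mean on a toy grid
  v <- matrix(as.numeric(1:25), 5)
  got <- rasterValues(focalMean(gridRaster(v), 1.5))
  expect_equal(got, bruteFocalMean(v, 1.5, 1), tolerance = 1e-12)
  # constant raster maps to itself; radius zero is the identity
  expect_equal(rasterValues(focalMean(constRaster(7), 2)),
               matrix(7, 5, 5))
  expect_equal(rasterValues(focalMean(gridRaster(v), 0)), v)
})

test_that("focal operators are translation-equivariant and monotone", {
  set.seed(6)
  m <- matrix(runif(400), 20, 20)
  r <- gridRaster(m)
  f1 <- rasterValues(focalMean(r, 2))
  shifted <- gridRaster(m[, c(20, 1:19)])
  f2 <- rasterValues(focalMean(shifted, 2))
  # interior columns are pure translations of each other
  expect_equal(f2[, 4:18], f1[, 3:17], tolerance = 1e-12)
  # adding positive cells never decreases the focal percentage
  b <- matrix(rbinom(400, 1, 0.2), 20, 20)
  p1 <- rasterValues(focalPercentage(gridRaster(b), 3))
  b2 <- b; b2[b2 == 0][1:20] <- 1
  p2 <- rasterValues(focalPercentage(gridRaster(b2), 3))
  expect_true(all(p2 - p1 >= -1e-12))
})

test_that("patch metrics reproduce hand-labelled cases", {
  # uniform single-class block
  u <- patchMetrics(constRaster(1, 4, 4), blockKm = 4)
  expect_true(all(rasterValues(u$fragmentation) == 1))
  expect_true(all(rasterValues(u$heterogeneity) == 1))
  # block split into two half-blocks of different classes: P=2, C=2
  m <- rbind(matrix(1, 2, 4), matrix(2, 2, 4))
  s <- patchMetrics(gridRaster(m), blockKm = 4)
  expect_true(all(rasterValues(s$fragmentation) == 1))
  expect_true(all(rasterValues(s$heterogeneity) == 4))
  # 2x2 checkerboard, 4-connectivity: P=4, C=2
  cb <- matrix(c(1, 2, 2, 1), 2, 2)
  s4 <- patchMetrics(gridRaster(cb), blockKm = 2)
  expect_true(all(rasterValues(s4$fragmentation) == 2))
  expect_true(all(rasterValues(s4$heterogeneity) == 8))
  # same block under 8-connectivity merges the diagonals: P=2, C=2
  s8 <- patchMetrics(gridRaster(cb), blockKm = 2, connectivity = 8)
  expect_true(all(rasterValues(s8$fragmentation) == 1))
  expect_true(all(rasterValues(s8$heterogeneity) == 4))
  # fully masked block yields NA
  mm <- matrix(NA_real_, 2, 2)
  sNA <- patchMetrics(gridRaster(mm), blockKm = 2)
  expect_true(all(is.na(rasterValues(sNA$fragmentation))))
})

test_that("patch metrics agree with an independent labelling oracle", {
  set.seed(7)
  m <- matrix(sample(1:3, 144, replace = TRUE), 12, 12)
  pm <- patchMetrics(gridRaster(m), blockKm = 6)
  for (bi in 1:2) for (bj in 1:2) {
    rs <- ((bi - 1) * 6 + 1):(bi * 6)
    cs <- ((bj - 1) * 6 + 1):(bj * 6)
    blk <- m[rs, cs]
    P <- brutePatchCount(blk)
    C <- length(unique(c(blk)))
    expect_equal(rasterValues(pm$fragmentation)[rs[1], cs[1]], P / C)
    expect_equal(rasterValues(pm$heterogeneity)[rs[1], cs[1]], P * C)
  }
  # heterogeneity = fragmentation * C^2 and both at least 1
  f <- rasterValues(pm$fragmentation); h <- rasterValues(pm$heterogeneity)
  expect_true(all(f >= 1) && all(h >= 1))
  C <- sqrt(h / f)                  # implied class count per block
  expect_true(all(abs(C - round(C)) < 1e-9))
})

test_that("minimum-distance maps are exact", {
  g <- gridRaster(matrix(0, 10, 10))
  # a point at a cell centre gives zero there
  d0 <- minDistanceMap(data.frame(x = 2.5, y = 2.5), g)
  expect_equal(rasterValues(d0)[8, 3], 0)   # row 8 is y = 2.5
  # 3-4-5 triangle: point at origin corner area, cell centre (3.5, 4.5)+off
  g2 <- gridRaster(matrix(0, 6, 6))
  d <- minDistanceMap(data.frame(x = 0.5, y = 0.5), g2)
  # cell centre at (3.5, 4.5): dx = 3, dy = 4 -> 5
  expect_equal(extractAt(d, 3.5, 4.5), 5)
  # random instance equals the all-pairs oracle everywhere
  set.seed(8)
  pts <- data.frame(x = runif(50, 0, 10), y = runif(50, 0, 10))
  got <- c(rasterValues(minDistanceMap(pts, g)))
  expect_equal(got, bruteMinDistance(g, pts), tolerance = 1e-12)
  # metres output
  dm <- minDistanceMap(pts, g, units = "m")
  expect_equal(c(rasterValues(dm)), 1000 * got, tolerance = 1e-9)
})

test_that("minimum distance respects the severity filter and Lipschitz bound", {
  g <- gridRaster(matrix(0, 15, 15))
  pts <- data.frame(x = c(2.5, 11.5), y = c(2.5, 11.5),
                    severity = c(1L, 4L))
  dAll <- minDistanceMap(pts, g)
  dHigh <- minDistanceMap(pts, g, minSeverity = 3)
  expect_true(all(rasterValues(dHigh) >= rasterValues(dAll) - 1e-12))
  expect_error(minDistanceMap(pts, g, minSeverity = 5), "severity")
  # adjacent cells differ by at most the cell diagonal
  v <- rasterValues(dAll)
  expect_true(all(abs(diff(v)) <= sqrt(2) + 1e-9))
  expect_true(all(abs(t(diff(t(v)))) <= sqrt(2) + 1e-9))
})

test_that("aspect categories follow the down-slope convention", {
  # elevation falling northward: every cell faces north
  nr <- 12
  zy <- matrix(rep(seq_len(nr), 12), nr)        # increases southward
  aN <- rasterValues(aspectCategory(gridRaster(100 * zy)))
  expect_true(all(aN == 1))
  # constant surface is all flat
  expect_true(all(rasterValues(aspectCategory(constRaster(5, 8, 8))) == 0))
  # synthetic cone: all four quadrants populated near-symmetrically
  n <- 101
  ctr <- (n + 1) / 2
  cone <- outer(seq_len(n), seq_len(n), function(r, cc)
    -sqrt((r - ctr)^2 + (cc - ctr)^2))
  a <- rasterValues(aspectCategory(gridRaster(cone)))
  counts <- table(factor(a[a > 0], levels = 1:4))
  expect_true(all(counts > 0))
  expect_lt(diff(range(counts)) / sum(counts), 0.02)
})
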