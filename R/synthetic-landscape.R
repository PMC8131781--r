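#' @include GridRaster-methods.R rng.R
NULL

# ---- internal field machinery -----------------------------------------

# circular (FFT) convolution of a matrix with a centred kernel image of the
# same size; used for random-field smoothing and disk dilation where the
# wrap-around is harmless
.fftConvolve <- function(mat, kern) {
  stopifnot(identical(dim(mat), dim(kern)))
  Re(stats::fft(stats::fft(mat) * stats::fft(kern), inverse = TRUE)) /
    length(mat)
}

# Gaussian kernel image centred on cell (1,1) with circular wrap
.gaussKernelImage <- function(nr, nc, sigmaCells) {
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  k <- exp(-outer(dr^2, dc^2, "+") / (2 * sigmaCells^2))
  k / sum(k)
}

# binary disk image centred on cell (1,1), circular wrap
.diskKernelImage <- function(nr, nc, radiusCells) {
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  (outer(dr^2, dc^2, "+") <= radiusCells^2 + 1e-9) * 1
}

# smoothed standard-normal field: white noise convolved with a Gaussian
# kernel of range sigmaCells, restandardized to mean 0 / sd 1
.smoothField <- function(nr, nc, sigmaCells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigmaCells > 1e-9) {
    k <- .gaussKernelImage(nr, nc, sigmaCells)
    z <- .fftConvolve(z, k)
  }
  (z - mean(z)) / stats::sd(z)
}

# symmetric PSD square root R with t(R) %*% R = C; errors on negative
# eigenvalues (beyond numerical jitter) so a bad target matrix is caught
.psdSqrt <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  if (any(e$values < -1e-8))
    stop("target correlation matrix is not positive semi-definite")
  v <- pmax(e$values, 0)
  diag(sqrt(v)) %*% t(e$vectors)
}

# ---- climate ----------------------------------------------------------

#' Generate a correlated stack of spatially autocorrelated climate fields
#'
#' Each layer starts as white noise convolved with a Gaussian kernel of the
#' stated range; layers are then empirically whitened and linearly mixed so
#' that the sample correlation matrix over cells equals the target exactly
#' (up to the rank of the target). Layers come out standardized (mean 0,
#' sd 1 over cells), emulating a set of partially collinear bioclimatic
#' layers.
#'
#' @param nRow,nCol grid dimensions.
#' @param cellKm cell edge length (km).
#' @param targetCor symmetric positive semi-definite correlation matrix; its
#'   dimension sets the number of layers.
#' @param autocorrRangeKm Gaussian kernel sd (km) controlling spatial
#'   autocorrelation.
#' @param seed integer seed.
#' @param names optional layer names; default `clim1..climK`.
#' @param origin lower-left grid corner (km).
#' @return named list of [GridRaster-class] layers.
#' @examples
#' cl <- generateClimate(60, 60, 1, diag(2), autocorrRangeKm = 5, seed = 1)
#' cor(c(rasterValues(cl[[1]])), c(rasterValues(cl[[2]])))
#' @export
generateClimate <- function(nRow, nCol, cellKm, targetCor,
                            autocorrRangeKm, seed,
                            names = NULL, origin = c(0, 0)) {
  targetCor <- as.matrix(targetCor)
  K <- nrow(targetCor)
  if (!isTRUE(all.equal(targetCor, t(targetCor), tolerance = 1e-8)))
    stop("target correlation matrix must be symmetric")
  R <- .psdSqrt(targetCor)   # errors if not PSD
  if (is.null(names)) names <- paste0("clim", seq_len(K))
  stopifnot(length(names) == K)
  sigmaCells <- autocorrRangeKm / cellKm
  withSubstream(seed, "climate", {
    X <- vapply(seq_len(K), function(j) c(.smoothField(nRow, nCol, sigmaCells)),
                numeric(nRow * nCol))
    # empirical whitening, then mixing: sample correlation == target
    W <- tryCatch(solve(chol(stats::cov(X))), error = function(e) NULL)
    if (!is.null(W)) X <- X %*% W
    Y <- X %*% R
    out <- lapply(seq_len(K), function(j) {
      v <- Y[, j]
      s <- stats::sd(v)
      if (s > 1e-12) v <- (v - mean(v)) / s
      gridRaster(matrix(v, nRow, nCol), cellKm = cellKm, origin = origin,
                 name = names[j])
    })
    names(out) <- names
    out
  })
}

# ---- habitat / host / dem ---------------------------------------------

#' Generate habitat classes, host cover and elevation
#'
#' Habitat classes come from the argmax of `nClasses` independent smoothed
#' Gaussian fields, which yields spatially clustered patches whose typical
#' size grows with `clusteringRangeKm`. Host presence is a smoothed field
#' thresholded at the `1 - hostPrevalence` quantile, so the realized host
#' fraction matches the requested prevalence up to grid discreteness. The
#' DEM is a smooth nonnegative surface (smoothed noise rescaled to
#' `demRange` metres).
#'
#' @param nRow,nCol grid dimensions.
#' @param cellKm cell edge length (km).
#' @param nClasses number of habitat classes (>= 1).
#' @param hostPrevalence target host cell fraction in (0, 1]; `1` fills the
#'   grid.
#' @param clusteringRangeKm Gaussian kernel sd (km); 0 gives i.i.d. classes.
#' @param seed integer seed.
#' @param demRange elevation range in metres, default `c(0, 1500)`.
#' @param origin lower-left grid corner (km).
#' @return list with `habitat`, `host`, `dem` [GridRaster-class] layers.
#' @export
generateHabitat <- function(nRow, nCol, cellKm, nClasses, hostPrevalence,
                            clusteringRangeKm, seed,
                            demRange = c(0, 1500), origin = c(0, 0)) {
  if (nClasses < 1) stop("'nClasses' must be >= 1")
  if (hostPrevalence <= 0 || hostPrevalence > 1)
    stop("'hostPrevalence' must be in (0, 1]")
  sigmaCells <- clusteringRangeKm / cellKm
  withSubstream(seed, "habitat", {
    fields <- lapply(seq_len(nClasses), function(i)
      .smoothField(nRow, nCol, sigmaCells))
    if (nClasses == 1L) {
      hab <- matrix(1, nRow, nCol)
    } else {
      A <- vapply(fields, c, numeric(nRow * nCol))
      hab <- matrix(max.col(A, ties.method = "first"), nRow, nCol)
    }
    hostField <- .smoothField(nRow, nCol, max(sigmaCells, 1e-9))
    if (hostPrevalence >= 1) {
      host <- matrix(1, nRow, nCol)
    } else {
      thr <- stats::quantile(hostField, 1 - hostPrevalence, names = FALSE)
      host <- (hostField > thr) * 1
    }
    demField <- .smoothField(nRow, nCol, max(2 * sigmaCells, 2))
    demv <- demField - min(demField)
    demv <- demRange[1] + demv / max(demv) * (demRange[2] - demRange[1])
    list(
      habitat = gridRaster(hab, cellKm, origin, "habitat"),
      host    = gridRaster(host, cellKm, origin, "host"),
      dem     = gridRaster(demv, cellKm, origin, "elevation")
    )
  })
}

#' Assemble a full synthetic landscape
#'
#' Convenience wrapper producing a [LandscapeBundle-class] with correlated
#' climate layers, clustered habitat, host cover and elevation from a
#' single seed.
#'
#' @param nRow,nCol,cellKm grid geometry.
#' @param targetCor climate correlation matrix (see [generateClimate()]).
#' @param autocorrRangeKm climate autocorrelation range (km).
#' @param nClasses,hostPrevalence,clusteringRangeKm habitat parameters
#'   (see [generateHabitat()]).
#' @param seed integer seed.
#' @param climNames optional climate layer names.
#' @param origin lower-left grid corner (km).
#' @return a [LandscapeBundle-class]
#' @export
makeLandscape <- function(nRow, nCol, cellKm = 0.5,
                          targetCor = diag(8), autocorrRangeKm = 8,
                          nClasses = 6, hostPrevalence = 0.25,
                          clusteringRangeKm = 3, seed = 1,
                          climNames = NULL, origin = c(0, 0)) {
  clim <- generateClimate(nRow, nCol, cellKm, targetCor, autocorrRangeKm,
                          seed = substreamSeed(seed, "clim"),
                          names = climNames, origin = origin)
  hab <- generateHabitat(nRow, nCol, cellKm, nClasses, hostPrevalence,
                         clusteringRangeKm,
                         seed = substreamSeed(seed, "hab"), origin = origin)
  landscapeBundle(clim, hab$host, hab$habitat, hab$dem)
}

# ---- truth ------------------------------------------------------------

#' True suitability of a virtual species over a climate stack
#'
#' Evaluates the generative logistic-quadratic niche
#' `s(x) = plogis(a0 + sum_j a1_j z_j + a2_j z_j^2)` cell-wise. By default
#' each layer is standardized over its own unmasked cells; explicit
#' `center`/`scale` (named vectors, or single values recycled) keep the
#' niche on a fixed absolute scale across regions whose local climate
#' distributions differ — essential when comparing a native and an invaded
#' region under one truth.
#'
#' @param truth a [VirtualSpeciesTruth-class]
#' @param climate named list of [GridRaster-class] layers.
#' @param center,scale optional standardization constants per layer.
#' @return a [GridRaster-class] of suitability values in (0, 1).
#' @export
trueSuitability <- function(truth, climate, center = NULL, scale = NULL) {
  vars <- names(truth@a1)
  missing <- setdiff(vars, names(climate))
  if (length(missing))
    stop("climate stack is missing layer(s): ", paste(missing, collapse = ", "))
  ref <- climate[[vars[1]]]
  eta <- matrix(truth@a0, nrow(ref@values), ncol(ref@values))
  for (j in vars) {
    v <- climate[[j]]@values
    ctr <- if (is.null(center)) mean(v, na.rm = TRUE)
           else if (length(center) == 1L) center else center[[j]]
    scl <- if (is.null(scale)) stats::sd(v, na.rm = TRUE)
           else if (length(scale) == 1L) scale else scale[[j]]
    z <- (v - ctr) / scl
    eta <- eta + truth@a1[[j]] * z + truth@a2[[j]] * z^2
  }
  gridRaster(stats::plogis(eta), ref@cellKm, ref@origin, "true_suitability")
}

# severity level from suitability + uniform jitter, via ordered cutpoints
.severityFromSuitability <- function(s, cutpoints, jitterHalfWidth = 0.05) {
  sj <- s + stats::runif(length(s), -jitterHalfWidth, jitterHalfWidth)
  1L + findInterval(sj, cutpoints)
}

# sampling weight per cell: suitability times host (if host-dependent),
# masked cells zero
.samplingWeights <- function(truth, landscape, suit) {
  w <- suit@values
  w[is.na(w)] <- 0
  if (truth@hostDependent) {
    h <- landscape@host@values
    h[is.na(h)] <- 0
    w <- w * h
  }
  w
}

# ---- occurrence sampling ----------------------------------------------

#' Sample equilibrium (native-range style) occurrences
#'
#' Draws occurrence cells with probability proportional to true suitability
#' times host presence (host factor only for host-dependent species),
#' emulating a species in pseudo-equilibrium that has filled its climatic
#' range. Severity levels are assigned from the truth's cutpoints applied
#' to suitability plus a small uniform jitter, so severity tracks climate
#' without being deterministic.
#'
#' @param truth a [VirtualSpeciesTruth-class]
#' @param landscape a [LandscapeBundle-class]
#' @param n number of records to draw.
#' @param seed integer seed.
#' @param year year tag for the records (default 0).
#' @param thin if `TRUE` (default) cells are drawn without replacement so
#'   each record is a distinct cell (one record per cell-year); `FALSE`
#'   draws with replacement and may duplicate cells.
#' @param suitability optional precomputed true-suitability raster.
#' @param center,scale optional standardization passed to
#'   [trueSuitability()].
#' @return occurrence data.frame (`x, y, year, severity, source`).
#' @export
sampleOccurrencesEquilibrium <- function(truth, landscape, n, seed,
                                         year = 0L, thin = TRUE,
                                         suitability = NULL,
                                         center = NULL, scale = NULL) {
  stopifnot(n >= 1)
  suit <- if (is.null(suitability))
    trueSuitability(truth, landscape@climate, center, scale) else suitability
  w <- .samplingWeights(truth, landscape, suit)
  pos <- which(w > 0)
  if (!length(pos))
    stop("no cell has positive sampling weight (suitability x host support is empty)")
  withSubstream(seed, "equilibrium", {
    if (thin) {
      k <- min(n, length(pos))
      cells <- pos[sample.int(length(pos), k, prob = w[pos])]
    } else {
      cells <- pos[sample.int(length(pos), n, replace = TRUE, prob = w[pos])]
    }
    xy <- cellCenters(suit, cells)
    sev <- .severityFromSuitability(suit@values[cells],
                                    truth@severityCutpoints)
    data.frame(x = xy$x, y = xy$y, year = as.integer(year),
               severity = as.integer(sev), source = "equilibrium",
               stringsAsFactors = FALSE)
  })
}

#' Simulate a dispersal-limited invasion
#'
#' Starting from introduction points, each year the set of candidate cells
#' is every unoccupied cell within the truth's dispersal radius of an
#' occupied cell; candidates become new occurrences with probability
#' proportional to suitability times host presence. The occupied set is
#' monotonically non-decreasing and every new record lies within the
#' dispersal radius of the previous year's front, emulating an invasion
#' front that has not yet filled its climatic niche.
#'
#' @param truth a [VirtualSpeciesTruth-class]
#' @param landscape a [LandscapeBundle-class]
#' @param introPoints data.frame with `x`, `y` of introduction sites (km).
#' @param nYears number of simulated years (year 1 = introduction).
#' @param perYearIntensity target number of new occurrences per year.
#' @param seed integer seed.
#' @param startYear calendar year of the introduction (default 1).
#' @param suitability optional precomputed true-suitability raster.
#' @param center,scale optional standardization passed to
#'   [trueSuitability()].
#' @return occurrence data.frame with one row per newly colonised cell-year.
#' @export
simulateInvasion <- function(truth, landscape, introPoints, nYears,
                             perYearIntensity, seed, startYear = 1L,
                             suitability = NULL,
                             center = NULL, scale = NULL) {
  stopifnot(nYears >= 1)
  suit <- if (is.null(suitability))
    trueSuitability(truth, landscape@climate, center, scale) else suitability
  w <- .samplingWeights(truth, landscape, suit)
  d <- dim(suit@values)
  introCells <- cellFromXY(suit, introPoints$x, introPoints$y)
  if (any(is.na(introCells)))
    stop("introduction points must lie on the landscape extent")
  introCells <- unique(introCells)
  radiusCells <- truth@dispersalRadiusKm / suit@cellKm
  # pad before the FFT so dilation does not wrap across grid edges
  pad <- ceiling(radiusCells) + 1L
  pd <- d + 2L * pad
  disk <- if (radiusCells > 0) .diskKernelImage(pd[1], pd[2], radiusCells)
          else NULL
  withSubstream(seed, "invasion", {
    occupied <- logical(prod(d))
    occupied[introCells] <- TRUE
    rows <- list()
    xy <- cellCenters(suit, introCells)
    rows[[1]] <- data.frame(
      x = xy$x, y = xy$y, year = as.integer(startYear),
      severity = as.integer(.severityFromSuitability(
        suit@values[introCells], truth@severityCutpoints)),
      source = "invasion", stringsAsFactors = FALSE)
    if (nYears > 1) for (t in 2:nYears) {
      if (is.null(disk)) {
        reach <- occupied  # zero radius: nothing new is reachable
      } else {
        occPad <- matrix(0, pd[1], pd[2])
        occPad[pad + seq_len(d[1]), pad + seq_len(d[2])] <-
          matrix(as.numeric(occupied), d[1], d[2])
        dil <- .fftConvolve(occPad, disk)
        reach <- c(dil[pad + seq_len(d[1]), pad + seq_len(d[2])]) > 0.5
      }
      cand <- which(reach & !occupied & w > 0)
      if (length(cand)) {
        k <- min(perYearIntensity, length(cand))
        newCells <- cand[sample.int(length(cand), k, prob = w[cand])]
        occupied[newCells] <- TRUE
        xy <- cellCenters(suit, newCells)
        rows[[t]] <- data.frame(
          x = xy$x, y = xy$y, year = as.integer(startYear + t - 1L),
          severity = as.integer(.severityFromSuitability(
            suit@values[newCells], truth@severityCutpoints)),
          source = "invasion", stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
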