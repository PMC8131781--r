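#' @include GridRaster-methods.R
NULL

# window offsets (dr, dc) whose cell-centre distance is within radius
.windowOffsets <- function(radiusKm, cellKm) {
  r <- radiusKm / cellKm
  k <- floor(r + 1e-9)
  if (k < 1) return(cbind(dr = 0L, dc = 0L))
  g <- expand.grid(dr = -k:k, dc = -k:k)
  g <- g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

# shrinking-window focal mean: per cell, mean of unmasked input over the
# circular window clipped to the grid (no padding, so border means are
# unbiased); masked cells excluded from numerator and denominator
.focalMeanMat <- function(mat, radiusKm, cellKm) {
  off <- .windowOffsets(radiusKm, cellKm)
  nr <- nrow(mat); nc <- ncol(mat)
  valid <- !is.na(mat)
  vals <- mat
  vals[!valid] <- 0
  num <- matrix(0, nr, nc)
  den <- matrix(0, nr, nc)
  for (i in seq_len(nrow(off))) {
    dr <- off[i, 1]; dc <- off[i, 2]
    rs <- max(1, 1 - dr):min(nr, nr - dr)   # destination rows
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    num[rs, cs] <- num[rs, cs] + vals[rs + dr, cs + dc]
    den[rs, cs] <- den[rs, cs] + valid[rs + dr, cs + dc]
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Focal percentage within a circular window
#'
#' Per cell, 100 times the mean of a binary (or fractional) input over all
#' cells whose centre lies within `radiusKm` of the focal cell centre.
#' Near grid borders the window shrinks to the available cells; masked
#' cells are excluded from both numerator and denominator. A radius smaller
#' than the cell size reduces to the input scaled by 100.
#'
#' @param x input [GridRaster-class] (values in `[0, 1]`).
#' @param radiusKm window radius (km), `>= 0`.
#' @param name output layer name.
#' @return percentage [GridRaster-class] in `[0, 100]`.
#' @export
focalPercentage <- function(x, radiusKm, name = paste0(x@name, "_pct")) {
  stopifnot(radiusKm >= 0)
  out <- 100 * .focalMeanMat(x@values, radiusKm, x@cellKm)
  gridRaster(out, x@cellKm, x@origin, name)
}

#' Focal mean within a circular window
#'
#' As [focalPercentage()] without the factor 100; used e.g. for mean basal
#' area within 1 km.
#'
#' @inheritParams focalPercentage
#' @return mean-value [GridRaster-class].
#' @export
focalMean <- function(x, radiusKm, name = paste0(x@name, "_mean")) {
  stopifnot(radiusKm >= 0)
  out <- .focalMeanMat(x@values, radiusKm, x@cellKm)
  gridRaster(out, x@cellKm, x@origin, name)
}

# connected components of equal-valued cells in a small integer matrix;
# NA cells are not part of any patch. Returns patch count.
.countPatches <- function(m, connectivity = 4) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nextLab <- 0L
  if (connectivity == 4) {
    nbr <- cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    nbr <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
    nbr <- nbr[!(nbr[, 1] == 0 & nbr[, 2] == 0), , drop = FALSE]
  }
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (is.na(m[r0, c0]) || lab[r0, c0] != 0L) next
    nextLab <- nextLab + 1L
    cls <- m[r0, c0]
    stack <- list(c(r0, c0))
    lab[r0, c0] <- nextLab
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (i in seq_len(nrow(nbr))) {
        rr <- p[1] + nbr[i, 1]; cc <- p[2] + nbr[i, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            lab[rr, cc] == 0L && !is.na(m[rr, cc]) && m[rr, cc] == cls) {
          lab[rr, cc] <- nextLab
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  nextLab
}

#' Per-block patch fragmentation and heterogeneity
#'
#' Tiles the habitat raster into square blocks of `blockKm` edge (anchored
#' at the raster origin; partial edge blocks use their available cells) and
#' computes per block the number of connected same-class patches `P` and
#' distinct classes `C`. Fragmentation is `P / C` (patches per class) and
#' heterogeneity `P * C`; both are broadcast back to cell resolution so the
#' outputs share the input grid. Fully masked blocks are `NA`.
#'
#' @param habitat integer-class [GridRaster-class].
#' @param blockKm block edge length (km); must be a multiple of the cell
#'   size.
#' @param connectivity 4 (default) or 8.
#' @return list of `fragmentation` and `heterogeneity`
#'   [GridRaster-class] layers.
#' @export
patchMetrics <- function(habitat, blockKm = 1, connectivity = 4) {
  b <- blockKm / habitat@cellKm
  if (abs(b - round(b)) > 1e-8)
    stop("'blockKm' must be an integer multiple of the cell size")
  b <- max(1L, as.integer(round(b)))
  m <- habitat@values
  nr <- nrow(m); nc <- ncol(m)
  frag <- matrix(NA_real_, nr, nc)
  het <- matrix(NA_real_, nr, nc)
  for (bi in seq_len(ceiling(nr / b))) for (bj in seq_len(ceiling(nc / b))) {
    rs <- ((bi - 1L) * b + 1L):min(bi * b, nr)
    cs <- ((bj - 1L) * b + 1L):min(bj * b, nc)
    blk <- m[rs, cs, drop = FALSE]
    if (all(is.na(blk))) next
    P <- .countPatches(blk, connectivity)
    C <- length(unique(blk[!is.na(blk)]))
    frag[rs, cs] <- P / C
    het[rs, cs] <- P * C
  }
  list(
    fragmentation = gridRaster(frag, habitat@cellKm, habitat@origin,
                               "fragmentation"),
    heterogeneity = gridRaster(het, habitat@cellKm, habitat@origin,
                               "heterogeneity")
  )
}

#' Minimum distance to a set of observation points
#'
#' Per cell, the Euclidean distance from the cell centre to the nearest
#' retained point. The standard dispersal covariates are distances to all
#' previous-year records (distribution model) and to high-severity records
#' only (severity model); the `minSeverity` filter implements the latter.
#'
#' @param points occurrence data.frame with `x`, `y` (and `severity` if
#'   filtering).
#' @param grid [GridRaster-class] defining the output geometry.
#' @param minSeverity optional: keep only records with
#'   `severity >= minSeverity`.
#' @param units `"km"` (default) or `"m"` for the output values.
#' @return distance [GridRaster-class].
#' @export
minDistanceMap <- function(points, grid, minSeverity = NULL, units = "km") {
  if (!is.null(minSeverity)) {
    points <- points[points$severity >= minSeverity, , drop = FALSE]
    if (!nrow(points))
      stop("no points remain with severity >= ", minSeverity)
  }
  if (!nrow(points)) stop("no points supplied for the distance map")
  ctr <- cellCenters(grid)
  n <- nrow(ctr)
  out <- numeric(n)
  chunk <- max(1L, floor(4e6 / max(1L, nrow(points))))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    d2 <- outer(ctr$x[idx], points$x, "-")^2 +
          outer(ctr$y[idx], points$y, "-")^2
    out[idx] <- sqrt(.rowMins(d2))
  }
  if (units == "m") out <- out * 1000
  vals <- matrix(out, nrow(grid@values), ncol(grid@values))
  vals[is.na(grid@values)] <- NA_real_
  gridRaster(vals, grid@cellKm, grid@origin,
             paste0("min_distance_", units))
}

.rowMins <- function(m) {
  out <- m[, 1]
  if (ncol(m) > 1) for (j in 2:ncol(m)) out <- pmin(out, m[, j])
  out
}

#' Aspect category from a DEM
#'
#' Slope direction from central-difference gradients, binned into the four
#' compass quadrants by the down-slope facing direction: N (315-45 deg),
#' E (45-135), S (135-225), W (225-315). Cells whose gradient magnitude is
#' below `flatTol` (m per km) are coded flat. One-sided differences are
#' used at grid borders. Codes: 0 = flat, 1 = N, 2 = E, 3 = S, 4 = W.
#'
#' @param dem elevation [GridRaster-class] in metres.
#' @param flatTol flatness tolerance on the gradient magnitude.
#' @return categorical [GridRaster-class] of integer codes.
#' @export
aspectCategory <- function(dem, flatTol = 1e-6) {
  z <- dem@values
  nr <- nrow(z); nc <- ncol(z)
  h <- dem@cellKm
  dzdx <- matrix(NA_real_, nr, nc)   # east gradient
  dzdy <- matrix(NA_real_, nr, nc)   # north gradient (row 1 = north)
  if (nc >= 3) dzdx[, 2:(nc - 1)] <- (z[, 3:nc] - z[, 1:(nc - 2)]) / (2 * h)
  if (nc >= 2) {
    dzdx[, 1] <- (z[, 2] - z[, 1]) / h
    dzdx[, nc] <- (z[, nc] - z[, nc - 1]) / h
  } else dzdx[] <- 0
  if (nr >= 3) dzdy[2:(nr - 1), ] <- (z[1:(nr - 2), ] - z[3:nr, ]) / (2 * h)
  if (nr >= 2) {
    dzdy[1, ] <- (z[1, ] - z[2, ]) / h
    dzdy[nr, ] <- (z[nr - 1, ] - z[nr, ]) / h
  } else dzdy[] <- 0
  east <- -dzdx; north <- -dzdy      # down-slope facing direction
  mag <- sqrt(east^2 + north^2)
  az <- (atan2(east, north) * 180 / pi) %% 360
  code <- matrix(0L, nr, nc)
  code[az >= 315 | az < 45] <- 1L
  code[az >= 45 & az < 135] <- 2L
  code[az >= 135 & az < 225] <- 3L
  code[az >= 225 & az < 315] <- 4L
  code[mag < flatTol] <- 0L
  code[is.na(z)] <- NA_integer_
  out <- matrix(as.numeric(code), nr, nc)
  gridRaster(out, dem@cellKm, dem@origin, "aspect")
}
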