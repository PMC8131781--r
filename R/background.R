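#' @include geo-features.R maxent-fit.R
NULL

#' Sample uniform background points
#'
#' Draws background cells uniformly over the valid cells of a mask raster
#' (cells that are neither `NA` nor zero). Sampling is without replacement
#' when the mask holds enough cells, otherwise with replacement (noted by a
#' message). Points are placed at cell centres.
#'
#' @param mask [GridRaster-class]; valid cells are non-`NA`, non-zero.
#' @param n number of points (default 10000).
#' @param seed integer seed.
#' @return data.frame with `x`, `y`, `cell`.
#' @export
sampleBackground <- function(mask, n = 10000, seed = 1) {
  v <- mask@values
  valid <- which(!is.na(v) & v != 0)
  if (!length(valid)) stop("background mask has no valid cell")
  withSubstream(seed, "background", {
    if (n <= length(valid)) {
      cells <- valid[sample.int(length(valid), n)]
    } else {
      message("background request exceeds valid cells; sampling with replacement")
      cells <- valid[sample.int(length(valid), n, replace = TRUE)]
    }
    xy <- cellCenters(mask, cells)
    data.frame(x = xy$x, y = xy$y, cell = cells)
  })
}

#' Sample background restricted to presence buffers
#'
#' Uniform background over the union of disks of radius `bufferKm` around
#' the presences, optionally intersected with a host-plant mask. This is
#' the background design that removes the dispersal-distance factor (every
#' background point is reachable) and, with the host mask, the host factor
#' from a model.
#'
#' @param presences data.frame with `x`, `y`.
#' @param grid [GridRaster-class] defining the geometry (and study mask).
#' @param bufferKm buffer radius (default 10, a yearly flight distance).
#' @param n number of points.
#' @param seed integer seed.
#' @param hostMask optional binary [GridRaster-class]; only host cells are
#'   allowed when given.
#' @return data.frame with `x`, `y`, `cell`.
#' @export
bufferedBackground <- function(presences, grid, bufferKm = 10, n = 10000,
                               seed = 1, hostMask = NULL) {
  if (!nrow(presences)) stop("no presences to buffer around")
  d <- minDistanceMap(presences, grid)
  allow <- d@values <= bufferKm
  allow[is.na(allow)] <- FALSE
  if (!is.null(hostMask)) {
    h <- hostMask@values
    allow <- allow & !is.na(h) & h != 0
  }
  if (!any(allow))
    stop("no valid cell inside the presence buffers",
         if (!is.null(hostMask)) " after host masking" else "")
  m <- gridRaster(allow * 1, grid@cellKm, grid@origin, "buffer_mask")
  sampleBackground(m, n, seed)
}

#' Native-model background weight
#'
#' Weight attached to an invaded-range background point with native-model
#' suitability `p`: `w(p) = 1 / (1 + (p / (1 - p))^2)`, with `w(1) = 0` by
#' continuity. The weight decreases strictly in `p`, so points the native
#' model deems unsuitable — likely true absences — keep full weight, while
#' suitable-but-unoccupied points (likely not-yet-reached sites) are
#' down-weighted.
#'
#' @param p suitability in `[0, 1]` (vectorized).
#' @return weights in `[0, 1]`.
#' @examples
#' gallienWeight(c(0, 0.5, 0.9))  # 1, 0.5, 1/82
#' @export
gallienWeight <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("'p' must lie in [0, 1]")
  out <- ifelse(p >= 1, 0, 1 / (1 + (p / (1 - p))^2))
  as.numeric(out)
}

#' Weight a background sample with a native-range model
#'
#' Predicts the native model at each background point and attaches the
#' corresponding weight. Presences are never weighted (their
#' likelihood terms always carry weight 1 in the fit).
#'
#' @param background data.frame of background covariates.
#' @param nativeModel a [MaxentModel-class] or [MaxentEnsemble-class]
#' @return data.frame with columns `p` (native suitability) and `weight`.
#' @export
weightBackground <- function(background, nativeModel) {
  p <- if (is(nativeModel, "MaxentEnsemble"))
    ensemblePredict(nativeModel, background)
  else maxentPredict(nativeModel, background)
  data.frame(p = p, weight = gallienWeight(p))
}
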