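#' @include AllGenerics.R
NULL

#' Create a GridRaster
#'
#' @param values numeric matrix of cell values; `NA` = masked cell. Row 1 is
#'   the northernmost row.
#' @param cellKm cell edge length in km.
#' @param origin x/y of the lower-left grid corner in km.
#' @param name layer name.
#' @return a [GridRaster-class]
#' @examples
#' r <- gridRaster(matrix(runif(25), 5), cellKm = 1)
#' gridDim(r)
#' @export
gridRaster <- function(values, cellKm = 1, origin = c(0, 0), name = "layer") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("GridRaster", values = values, cellKm = cellKm,
      origin = as.numeric(origin), name = name)
}

#' @rdname rasterValues
#' @export
setMethod("rasterValues", "GridRaster", function(x) x@values)

#' @rdname cellSizeKm
#' @export
setMethod("cellSizeKm", "GridRaster", function(x) x@cellKm)

#' @rdname cellSizeKm
#' @export
setMethod("cellSizeKm", "LandscapeBundle", function(x) x@climate[[1L]]@cellKm)

#' @rdname gridDim
#' @export
setMethod("gridDim", "GridRaster", function(x) dim(x@values))

#' @rdname gridDim
#' @export
setMethod("gridDim", "LandscapeBundle", function(x) dim(x@climate[[1L]]@values))

#' @rdname layerName
#' @export
setMethod("layerName", "GridRaster", function(x) x@name)

#' @rdname layerName
#' @export
setReplaceMethod("layerName", "GridRaster", function(x, value) {
  x@name <- value
  validObject(x)
  x
})

setMethod("show", "GridRaster", function(object) {
  d <- dim(object@values)
  nmask <- sum(is.na(object@values))
  rng <- suppressWarnings(range(object@values, na.rm = TRUE))
  cat("GridRaster '", object@name, "': ", d[1], " x ", d[2],
      " cells @ ", object@cellKm, " km\n", sep = "")
  cat("  extent: x [", object@origin[1], ", ",
      object@origin[1] + d[2] * object@cellKm, "] y [",
      object@origin[2], ", ", object@origin[2] + d[1] * object@cellKm,
      "] km\n", sep = "")
  if (all(is.na(object@values))) {
    cat("  all cells masked\n")
  } else {
    cat("  values: [", signif(rng[1], 5), ", ", signif(rng[2], 5),
        "], ", nmask, " masked\n", sep = "")
  }
})

setMethod("show", "LandscapeBundle", function(object) {
  d <- gridDim(object)
  cat("LandscapeBundle: ", d[1], " x ", d[2], " cells @ ",
      cellSizeKm(object), " km\n", sep = "")
  cat("  climate layers: ", paste(names(object@climate), collapse = ", "),
      "\n", sep = "")
  cat("  host prevalence: ",
      signif(mean(object@host@values, na.rm = TRUE), 3), "\n", sep = "")
  cat("  habitat classes: ",
      length(unique(stats::na.omit(c(object@habitat@values)))), "\n", sep = "")
})

setMethod("show", "VirtualSpeciesTruth", function(object) {
  cat("VirtualSpeciesTruth over ", length(object@a1), " climate variables (",
      paste(names(object@a1), collapse = ", "), ")\n", sep = "")
  cat("  host-dependent: ", object@hostDependent,
      "; dispersal radius: ", object@dispersalRadiusKm, " km\n", sep = "")
  cat("  severity cutpoints: ",
      paste(object@severityCutpoints, collapse = ", "), "\n", sep = "")
})

setMethod("show", "MaxentModel", function(object) {
  nz <- sum(abs(object@coef) > 1e-12)
  cat("MaxentModel (", object@transform, " output): ",
      length(object@coef), " features, ", nz, " non-zero, beta = ",
      object@beta, "\n", sep = "")
  cat("  variables: ",
      paste(names(object@featureMap$variables), collapse = ", "), "\n",
      sep = "")
})

setMethod("show", "MaxentEnsemble", function(object) {
  cat("MaxentEnsemble of ", length(object@models), " replicates (train ",
      round(100 * object@meta$trainFraction), "%)\n", sep = "")
  if (nrow(object@evaluation)) {
    cat("  mean held-out AUC: ",
        signif(mean(object@evaluation$auc, na.rm = TRUE), 3),
        ", mean CBI: ",
        signif(mean(object@evaluation$cbi, na.rm = TRUE), 3), "\n", sep = "")
  }
})

#' Cell-centre coordinates
#'
#' @param x a [GridRaster-class]
#' @param cells optional integer vector of cell indices (column-major, as
#'   used by R matrices); default all cells.
#' @return data.frame with `x`, `y` cell-centre coordinates in km.
#' @export
cellCenters <- function(x, cells = NULL) {
  d <- dim(x@values)
  if (is.null(cells)) cells <- seq_len(prod(d))
  row <- (cells - 1L) %% d[1] + 1L
  col <- (cells - 1L) %/% d[1] + 1L
  data.frame(
    x = x@origin[1] + (col - 0.5) * x@cellKm,
    y = x@origin[2] + (d[1] - row + 0.5) * x@cellKm
  )
}

#' Cell index from planar coordinates
#'
#' @param x a [GridRaster-class]
#' @param px,py coordinate vectors in km.
#' @return integer cell indices (column-major); `NA` for points off-grid.
#' @export
cellFromXY <- function(x, px, py) {
  d <- dim(x@values)
  col <- ceiling((px - x@origin[1]) / x@cellKm)
  row <- d[1] - ceiling((py - x@origin[2]) / x@cellKm) + 1L
  # points exactly on the lower/left edge fall into the first cell
  col[px == x@origin[1]] <- 1L
  row[py == x@origin[2]] <- d[1]
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1]
  idx <- (col - 1L) * d[1] + row
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Extract raster values at points
#'
#' @param x a [GridRaster-class] or named list of them.
#' @param px,py coordinate vectors in km.
#' @return numeric vector, or a data.frame with one column per layer.
#' @export
extractAt <- function(x, px, py) {
  if (is(x, "GridRaster")) {
    idx <- cellFromXY(x, px, py)
    out <- rep(NA_real_, length(px))
    ok <- !is.na(idx)
    out[ok] <- x@values[idx[ok]]
    return(out)
  }
  as.data.frame(lapply(x, extractAt, px = px, py = py))
}

#' Construct a LandscapeBundle
#'
#' @param climate named list of [GridRaster-class] climate layers.
#' @param host binary host-plant [GridRaster-class].
#' @param habitat integer habitat-class [GridRaster-class].
#' @param dem elevation [GridRaster-class] (m).
#' @return a [LandscapeBundle-class]
#' @export
landscapeBundle <- function(climate, host, habitat, dem) {
  new("LandscapeBundle", climate = climate, host = host,
      habitat = habitat, dem = dem)
}

#' Construct a VirtualSpeciesTruth
#'
#' @param a0 intercept.
#' @param a1,a2 named linear and quadratic coefficients per climate layer
#'   (`a2 <= 0`).
#' @param hostDependent require the host plant for occurrence?
#' @param dispersalRadiusKm maximum yearly spread (km).
#' @param severityCutpoints 3 increasing suitability thresholds in (0,1).
#' @param seed integer seed stored with the truth.
#' @return a [VirtualSpeciesTruth-class]
#' @export
virtualSpeciesTruth <- function(a0, a1, a2, hostDependent = TRUE,
                                dispersalRadiusKm = 10,
                                severityCutpoints = c(0.25, 0.5, 0.75),
                                seed = 1L) {
  new("VirtualSpeciesTruth", a0 = a0, a1 = a1, a2 = a2,
      hostDependent = hostDependent,
      dispersalRadiusKm = dispersalRadiusKm,
      severityCutpoints = severityCutpoints, seed = as.integer(seed))
}
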