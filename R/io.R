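#' @include GridRaster-methods.R
NULL

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text single-band grid with the standard 6-line header; cell size
#' and corner coordinates are in kilometres (the package's planar unit)
#' and masked cells are written as the nodata sentinel.
#'
#' @param raster a [GridRaster-class]
#' @param path output file path.
#' @param nodata sentinel for masked cells (default -9999).
#' @return `path`, invisibly.
#' @export
writeRaster <- function(raster, path, nodata = -9999) {
  v <- raster@values
  d <- dim(v)
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", d[2]),
    paste("nrows", d[1]),
    paste("xllcorner", format(raster@origin[1], digits = 15)),
    paste("yllcorner", format(raster@origin[2], digits = 15)),
    paste("cellsize", format(raster@cellKm, digits = 15)),
    paste("NODATA_value", nodata)
  ), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param name layer name for the result (default: file stem).
#' @return a [GridRaster-class]
#' @export
readRaster <- function(path, name = NULL) {
  lines <- readLines(path, n = 6)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- stats::setNames(
    vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
    tolower(vapply(kv, `[[`, character(1), 1)))
  nHeader <- if ("nodata_value" %in% names(hdr)) 6L else 5L
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: ", path)
  vals <- scan(path, skip = nHeader, quiet = TRUE)
  m <- matrix(vals, nrow = hdr[["nrows"]], ncol = hdr[["ncols"]],
              byrow = TRUE)
  if ("nodata_value" %in% names(hdr))
    m[m == hdr[["nodata_value"]]] <- NA_real_
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  gridRaster(m, cellKm = hdr[["cellsize"]],
             origin = c(hdr[["xllcorner"]], hdr[["yllcorner"]]),
             name = name)
}

#' Assemble a named raster stack from files
#'
#' Reads several ASCII grids and verifies they share one geometry.
#'
#' @param paths named character vector of file paths.
#' @return named list of [GridRaster-class] layers.
#' @export
readRasterStack <- function(paths) {
  stack <- lapply(seq_along(paths), function(i)
    readRaster(paths[[i]], name = names(paths)[i]))
  names(stack) <- names(paths)
  ref <- stack[[1L]]
  for (i in seq_along(stack))
    if (!.sameGeometry(ref, stack[[i]]))
      stop("raster geometry mismatch between '", names(paths)[1],
           "' and '", names(paths)[i], "'")
  stack
}

#' Read an occurrence CSV
#'
#' Expects columns `x, y, year, severity[, source]`. Rows with missing
#' coordinates or year are dropped (with a message counting them); exact
#' duplicate `(x, y, year)` rows are collapsed; optionally records are
#' thinned to one per grid cell and year, the treatment applied to
#' spatially clustered field records.
#'
#' @param path CSV path.
#' @param dedupe collapse exact duplicate locations (default TRUE).
#' @param thinGrid optional [GridRaster-class]; thin to one record per
#'   cell-year on its geometry.
#' @return occurrence data.frame.
#' @export
readOccurrences <- function(path, dedupe = TRUE, thinGrid = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "year", "severity")
  if (!all(need %in% names(df)))
    stop("occurrence file must have columns ", paste(need, collapse = ", "))
  if (!"source" %in% names(df)) df$source <- "observed"
  bad <- !is.finite(df$x) | !is.finite(df$y) | !is.finite(df$year)
  if (any(bad)) {
    message("dropping ", sum(bad), " record(s) with missing coordinates or year")
    df <- df[!bad, , drop = FALSE]
  }
  if (dedupe) {
    df <- df[!duplicated(df[, c("x", "y", "year")]), , drop = FALSE]
  }
  if (!is.null(thinGrid)) {
    cell <- cellFromXY(thinGrid, df$x, df$y)
    df <- df[!duplicated(data.frame(cell, df$year)), , drop = FALSE]
  }
  if (!nrow(df)) stop("no occurrence records remain after filtering")
  rownames(df) <- NULL
  df
}

#' Write an occurrence CSV
#'
#' @param occ occurrence data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeOccurrences <- function(occ, path) {
  utils::write.csv(occ[, c("x", "y", "year", "severity", "source")],
                   path, row.names = FALSE)
  invisible(path)
}

# ---- model serialization ----------------------------------------------

.modelToList <- function(model) {
  list(coef = as.list(model@coef), beta = model@beta,
       regScale = as.list(model@regScale),
       featureMap = model@featureMap, logZ = model@logZ,
       entropy = model@entropy, transform = model@transform,
       meta = model@meta)
}

#' Serialize a fitted model to JSON
#'
#' Stores coefficients, the feature map, regularization scales, the
#' partition constant and the output transform; [readMaxentModel()]
#' restores a model that predicts identically.
#'
#' @param model a [MaxentModel-class]
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeMaxentModel <- function(model, path) {
  jsonlite::write_json(.modelToList(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeMaxentModel
#' @return for `readMaxentModel`, the restored [MaxentModel-class].
#' @export
readMaxentModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fm <- x$featureMap
  fm$variables <- lapply(fm$variables, as.list)
  new("MaxentModel", coef = unlist(x$coef), beta = x$beta,
      regScale = unlist(x$regScale), featureMap = fm,
      logZ = x$logZ, entropy = x$entropy, transform = x$transform,
      meta = as.list(x$meta))
}

#' Canonical JSON serialization of a model suite
#'
#' Coefficients of every replicate plus all evaluation numbers, with a
#' fixed key order — byte-identical for identical fits, the basis of the
#' end-to-end determinism check.
#'
#' @param suite a `modelSuite` list.
#' @return single JSON string.
#' @export
suiteToJSON <- function(suite) {
  models <- lapply(suite$models, function(ens) {
    if (is(ens, "MaxentEnsemble"))
      lapply(ens@models, function(m) as.list(round(m@coef, 10)))
    else as.list(round(ens@coef, 10))
  })
  evals <- lapply(suite$evaluations, function(e)
    list(auc = round(e$auc, 10), cbi = round(e$cbi, 10),
         region = e$region))
  as.character(jsonlite::toJSON(list(models = models, evaluations = evals),
                                auto_unbox = TRUE, digits = NA))
}
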