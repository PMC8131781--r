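#' @include AllClasses.R
NULL

#' Cell values of a raster
#' @param x a [GridRaster-class]
#' @return the numeric value matrix (row 1 = north).
#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' Cell edge length in kilometres
#' @param x a [GridRaster-class] or [LandscapeBundle-class]
#' @return single numeric, km.
#' @export
setGeneric("cellSizeKm", function(x) standardGeneric("cellSizeKm"))

#' Grid dimensions
#' @param x a [GridRaster-class] or [LandscapeBundle-class]
#' @return integer `c(nrow, ncol)`.
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' Layer name
#' @param x a [GridRaster-class]
#' @return single string.
#' @export
setGeneric("layerName", function(x) standardGeneric("layerName"))

#' @rdname layerName
#' @param value replacement name
#' @export
setGeneric("layerName<-", function(x, value) standardGeneric("layerName<-"))
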