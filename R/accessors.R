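# Accessor generics and show methods for the core classes.

#' @rdname GridRaster-class
#' @param object,x a GridRaster.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname GridRaster-class
#' @export
setMethod("gridValues", "GridRaster", function(x) x@values)

#' @rdname GridRaster-class
#' @param value replacement matrix of identical dimensions.
#' @export
setGeneric("gridValues<-", function(x, value) standardGeneric("gridValues<-"))

#' @rdname GridRaster-class
#' @export
setMethod("gridValues<-", "GridRaster", function(x, value) {
  value <- as.matrix(value)
  storage.mode(value) <- "double"
  x@values <- value
  validObject(x)
  x
})

#' @rdname GridRaster-class
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname GridRaster-class
#' @export
setMethod("cellSize", "GridRaster", function(x) x@cellsize)

#' @rdname GridRaster-class
#' @export
setGeneric("noDataValue", function(x) standardGeneric("noDataValue"))

#' @rdname GridRaster-class
#' @export
setMethod("noDataValue", "GridRaster", function(x) x@nodata)

#' @rdname GridRaster-class
#' @export
setMethod("dim", "GridRaster", function(x) c(x@nrows, x@ncols))

setMethod("show", "GridRaster", function(object) {
  v <- object@values
  cat(sprintf("GridRaster: %d rows x %d cols, cellsize %g\n",
              object@nrows, object@ncols, object@cellsize))
  cat(sprintf("  lower-left corner (%g, %g), nodata %g\n",
              object@xllcorner, object@yllcorner, object@nodata))
  ok <- !is.na(v)
  if (any(ok))
    cat(sprintf("  values: min %g, max %g, NA cells %d\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  else cat("  values: all NA\n")
})

#' @rdname LandscapeStack-class
#' @param x a LandscapeStack.
#' @param name one of "dem", "ndsm", "otm", "understoryHeight",
#'   "understoryOtm", "mask".
#' @export
setGeneric("stackLayer", function(x, name) standardGeneric("stackLayer"))

#' @rdname LandscapeStack-class
#' @export
setMethod("stackLayer", "LandscapeStack", function(x, name) {
  name <- match.arg(name, c("dem", "ndsm", "otm", "understoryHeight",
                            "understoryOtm", "mask"))
  slot(x, name)
})

#' @rdname LandscapeStack-class
#' @export
setGeneric("stackCeiling", function(x) standardGeneric("stackCeiling"))

#' @rdname LandscapeStack-class
#' @export
setMethod("stackCeiling", "LandscapeStack", function(x) x@ceiling)

#' @rdname LandscapeStack-class
#' @export
setMethod("dim", "LandscapeStack", function(x) dim(.stackTemplate(x)))

setMethod("show", "LandscapeStack", function(object) {
  present <- Filter(function(nm) !is.null(slot(object, nm)),
                    c("dem", "ndsm", "otm", "understoryHeight",
                      "understoryOtm", "mask"))
  tpl <- .stackTemplate(object)
  cat(sprintf("LandscapeStack: %d x %d cells at %g m, ceiling %.2f m\n",
              tpl@nrows, tpl@ncols, tpl@cellsize, object@ceiling))
  cat("  layers:", paste(present, collapse = ", "), "\n")
})

setMethod("show", "SunState", function(object) {
  cat(sprintf(
    "SunState %s: azimuth %.2f deg, altitude %.2f deg, EI %.1f, EIcos %.1f W/m2%s\n",
    format(object@timestamp, "%Y-%m-%d %H:%M"), object@azimuth,
    object@altitude, object@EI, object@EIcos,
    if (object@altitude <= 0) " (night)" else ""))
})

setMethod("show", "ShadeFields", function(object) {
  cat(sprintf("ShadeFields %s%s: %d x %d cells\n",
              format(object@sun@timestamp, "%Y-%m-%d %H:%M"),
              if (object@isNight) " (night)" else "",
              nrow(object@energy), ncol(object@energy)))
  e <- object@energy[!is.na(object@energy)]
  if (length(e))
    cat(sprintf("  energy: mean %.1f, max %.1f W/m2; mean total shade %.3f\n",
                mean(e), max(e),
                mean(object@totalShade, na.rm = TRUE)))
})

setMethod("show", "AggregatedOutputs", function(object) {
  cat(sprintf("AggregatedOutputs [%s .. %s], mode %s, units %s\n",
              format(object@windowStart, "%Y-%m-%d %H:%M"),
              format(object@windowEnd, "%Y-%m-%d %H:%M"),
              object@mode, object@units))
  cat(sprintf("  %d daylight timesteps; mean energy %.2f\n", object@nDaylight,
              mean(object@energy, na.rm = TRUE)))
})

setMethod("show", "CalibrationParams", function(object) {
  cat(sprintf("CalibrationParams: csCali %.4g, trCali %.4g, grCali %.4g\n",
              object@csCali, object@trCali, object@grCali))
})

setMethod("show", "FitStats", function(object) {
  cat(sprintf(
    "FitStats (n = %d): percent-agreement %.3f, mean-error %.2f, RMSE %.2f\n",
    object@n, object@percentAgreement, object@meanError, object@rmse))
})
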