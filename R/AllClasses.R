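#' @import methods
NULL

#' GridRaster: a georeferenced 2-D cell array
#'
#' Carrier for all raster layers (elevation, object height, transmittance)
#' and all gridded outputs. Values are stored north-to-south by row
#' (row 1 = northernmost) and west-to-east by column, matching the top-down
#' row order of the ESRI ASCII Grid format. Cells equal to the nodata
#' sentinel on disk are held as \code{NA} in \code{values}; the sentinel is
#' kept in \code{nodata} and restored on write.
#'
#' @slot ncols,nrows grid dimensions (>= 1).
#' @slot xllcorner,yllcorner map coordinates of the lower-left corner of the
#'   lower-left cell, in the same units as \code{cellsize}.
#' @slot cellsize cell edge length in metres (> 0); cells are square.
#' @slot nodata numeric sentinel written for missing cells.
#' @slot values numeric matrix of dimension \code{nrows x ncols}.
#'
#' @seealso [readAsciiGrid()], [writeAsciiGrid()], [LandscapeStack()]
#' @export
setClass("GridRaster",
  representation(
    ncols = "integer", nrows = "integer",
    xllcorner = "numeric", yllcorner = "numeric",
    cellsize = "numeric", nodata = "numeric",
    values = "matrix"
  )
)

setValidity("GridRaster", function(object) {
  msg <- character()
  if (length(object@ncols) != 1L || object@ncols < 1L)
    msg <- c(msg, "ncols must be a single integer >= 1")
  if (length(object@nrows) != 1L || object@nrows < 1L)
    msg <- c(msg, "nrows must be a single integer >= 1")
  if (length(object@cellsize) != 1L || !is.finite(object@cellsize) ||
      object@cellsize <= 0)
    msg <- c(msg, "cellsize must be > 0")
  if (!identical(dim(object@values),
                 c(as.integer(object@nrows), as.integer(object@ncols))))
    msg <- c(msg, sprintf("values must be a %d x %d matrix",
                          object@nrows, object@ncols))
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be numeric")
  if (length(msg)) msg else TRUE
})

#' Construct a GridRaster
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param cellsize cell edge length in metres.
#' @param xllcorner,yllcorner lower-left corner coordinates.
#' @param nodata nodata sentinel used on write (default -9999).
#' @return a validated [GridRaster-class] object.
#' @examples
#' g <- GridRaster(matrix(0, 4, 5), cellsize = 10)
#' dim(gridValues(g))
#' @export
GridRaster <- function(values, cellsize, xllcorner = 0, yllcorner = 0,
                       nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("GridRaster",
      ncols = ncol(values), nrows = nrow(values),
      xllcorner = as.numeric(xllcorner), yllcorner = as.numeric(yllcorner),
      cellsize = as.numeric(cellsize), nodata = as.numeric(nodata),
      values = values)
}

#' LandscapeStack: validated, co-registered raster layers
#'
#' Holds the elevation (DEM), object-height (nDSM) and object-transmittance
#' (OTM) layers, optional understory layers, and an optional area-of-interest
#' mask, all sharing identical geometry. The \code{ceiling} is precomputed as
#' the cell-wise maximum of elevation plus object height over non-missing
#' cells; a ray above the ceiling can never be intercepted, which bounds every
#' walk.
#'
#' @slot dem,ndsm,otm,understoryHeight,understoryOtm,mask layers
#'   ([GridRaster-class] or \code{NULL}); at least one of dem/ndsm present,
#'   otm required whenever ndsm is present. Mask cells > 0 select walk
#'   origins; unmasked cells still cast shade.
#' @slot ceiling maximum of (dem + ndsm) over cells, metres.
#' @seealso [LandscapeStack()], [simulateTimestep()]
#' @export
setClass("LandscapeStack",
  representation(
    dem = "ANY", ndsm = "ANY", otm = "ANY",
    understoryHeight = "ANY", understoryOtm = "ANY", mask = "ANY",
    ceiling = "numeric"
  )
)

.isGridOrNull <- function(x) is.null(x) || is(x, "GridRaster")

setValidity("LandscapeStack", function(object) {
  msg <- character()
  layers <- list(dem = object@dem, ndsm = object@ndsm, otm = object@otm,
                 understoryHeight = object@understoryHeight,
                 understoryOtm = object@understoryOtm, mask = object@mask)
  for (nm in names(layers))
    if (!.isGridOrNull(layers[[nm]]))
      msg <- c(msg, sprintf("layer '%s' must be a GridRaster or NULL", nm))
  if (length(msg)) return(msg)
  if (is.null(object@dem) && is.null(object@ndsm))
    msg <- c(msg, "at least one of dem, ndsm must be present")
  if (!is.null(object@ndsm) && is.null(object@otm))
    msg <- c(msg, "otm is required whenever ndsm is present")
  present <- Filter(Negate(is.null), layers)
  if (length(present) > 1L) {
    ref <- present[[1L]]
    for (nm in names(present)[-1L]) {
      bad <- .geometryMismatch(ref, present[[nm]])
      if (length(bad))
        msg <- c(msg, sprintf(
          "layer '%s' is not co-registered with '%s': %s differ",
          nm, names(present)[1L], paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(object@otm)) {
    v <- object@otm@values
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(v))
      msg <- c(msg, sprintf(
        "otm values must lie in [0, 1]; first offender %g at cell (%d, %d)",
        v[bad[1L]], rc[1L], rc[2L]))
    }
  }
  if (!is.null(object@ndsm)) {
    v <- object@ndsm@values
    if (any(!is.na(v) & v < 0))
      msg <- c(msg, "ndsm heights must be >= 0")
  }
  if (!is.null(object@understoryHeight)) {
    uh <- object@understoryHeight@values
    if (any(!is.na(uh) & uh < 0))
      msg <- c(msg, "understory heights must be >= 0")
    if (!is.null(object@ndsm)) {
      nd <- object@ndsm@values
      both <- !is.na(uh) & !is.na(nd)
      if (any(uh[both] > nd[both] + 1e-9))
        msg <- c(msg, "understory height must not exceed ndsm height")
    }
  }
  if (!is.null(object@understoryOtm)) {
    v <- object@understoryOtm@values
    if (any(!is.na(v) & (v < 0 | v > 1)))
      msg <- c(msg, "understory transmittance values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' SunState: one timestep's solar geometry and incident energy
#'
#' @slot timestamp local civil time of the step (POSIXct).
#' @slot azimuth sun bearing, degrees clockwise from north, [0, 360).
#' @slot altitude sun elevation above the horizon, degrees.
#' @slot EI top-of-atmosphere clear-sky irradiance, W/m2.
#' @slot EIcos cosine-corrected, calibrated incident energy, W/m2;
#'   zero whenever the sun is at or below the horizon.
#' @seealso [sunState()], [solarPosition()]
#' @export
setClass("SunState",
  representation(timestamp = "POSIXct", azimuth = "numeric",
                 altitude = "numeric", EI = "numeric", EIcos = "numeric")
)

setValidity("SunState", function(object) {
  msg <- character()
  if (object@EI < 0) msg <- c(msg, "EI must be >= 0")
  if (object@EIcos < -1e-9) msg <- c(msg, "EIcos must be >= 0")
  if (object@altitude <= 0 && object@EIcos > 1e-9)
    msg <- c(msg, "EIcos must be 0 when the sun is below the horizon")
  if (object@azimuth < 0 || object@azimuth >= 360)
    msg <- c(msg, "azimuth must lie in [0, 360)")
  if (length(msg)) msg else TRUE
})

#' SolarContext: site location and timing conventions
#'
#' @slot latitude degrees north, [-90, 90].
#' @slot longitude degrees east-positive, [-180, 180].
#' @slot utcOffset hours ahead of UTC for the civil timestamps supplied to
#'   the solar functions.
#' @slot solarConstant W/m2, default 1367.
#' @seealso [SolarContext()], [solarPosition()]
#' @export
setClass("SolarContext",
  representation(latitude = "numeric", longitude = "numeric",
                 utcOffset = "numeric", solarConstant = "numeric")
)

setValidity("SolarContext", function(object) {
  msg <- character()
  if (abs(object@latitude) > 90) msg <- c(msg, "latitude must lie in [-90, 90]")
  if (abs(object@longitude) > 180)
    msg <- c(msg, "longitude must lie in [-180, 180]")
  if (object@solarConstant <= 0) msg <- c(msg, "solarConstant must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SolarContext
#' @param latitude degrees north.
#' @param longitude degrees east-positive.
#' @param utcOffset hours ahead of UTC of the civil clock used for timestamps.
#' @param solarConstant solar constant, W/m2.
#' @return a [SolarContext-class] object.
#' @examples
#' SolarContext(44.916, -123.001, utcOffset = -8)
#' @export
SolarContext <- function(latitude, longitude, utcOffset = 0,
                         solarConstant = 1367) {
  new("SolarContext", latitude = as.numeric(latitude),
      longitude = as.numeric(longitude), utcOffset = as.numeric(utcOffset),
      solarConstant = as.numeric(solarConstant))
}

#' ShadeFields: per-timestep shade and energy grids
#'
#' All shade grids are fractions in [0, 1]; energy is in W/m2. Night
#' timesteps carry the convention object light = 1, terrain shade = 0,
#' energy = 0 and are flagged so aggregation can exclude them from shade
#' averages.
#'
#' @slot objectLight accumulated object light fraction per cell (product of
#'   encountered transmittances).
#' @slot objectShade 1 - objectLight.
#' @slot terrainShade terrain shade magnitude per cell.
#' @slot totalShade 1 - objectLight * (1 - terrainShade).
#' @slot energy ground-level incident energy, W/m2.
#' @slot sun the [SunState-class] of the timestep.
#' @slot isNight logical flag.
#' @slot template a [GridRaster-class] supplying geometry for export.
#' @seealso [composeShadeEnergy()], [aggregateFields()]
#' @export
setClass("ShadeFields",
  representation(objectLight = "matrix", objectShade = "matrix",
                 terrainShade = "matrix", totalShade = "matrix",
                 energy = "matrix", sun = "SunState", isNight = "logical",
                 template = "GridRaster")
)

setValidity("ShadeFields", function(object) {
  msg <- character()
  d <- dim(object@objectLight)
  for (nm in c("objectShade", "terrainShade", "totalShade", "energy"))
    if (!identical(dim(slot(object, nm)), d))
      msg <- c(msg, sprintf("grid '%s' does not match objectLight dimensions", nm))
  rng <- function(m) range(m[!is.na(m)], na.rm = TRUE)
  for (nm in c("objectLight", "objectShade", "terrainShade", "totalShade")) {
    m <- slot(object, nm)
    if (any(!is.na(m) & (m < -1e-9 | m > 1 + 1e-9)))
      msg <- c(msg, sprintf("grid '%s' must lie in [0, 1]", nm))
  }
  if (any(!is.na(object@energy) & object@energy < -1e-9))
    msg <- c(msg, "energy must be >= 0")
  if (length(msg)) msg else TRUE
})

#' AggregatedOutputs: time-aggregated shade and energy grids
#'
#' Shade grids are averages over daylight timesteps only; the energy grid is
#' either the mean power over all timesteps of the window (W/m2, nights
#' counting as zero) or the accumulated energy (J/m2 = W/m2 x s).
#'
#' @slot objectShade,terrainShade,totalShade daylight-mean shade fractions.
#' @slot energy aggregated energy grid.
#' @slot mode "mean" or "accumulated".
#' @slot units "W" (W/m2 or J/m2) or "PAR" (umol/m2/s after conversion).
#' @slot windowStart,windowEnd POSIXct bounds of the aggregation window.
#' @slot nDaylight number of daylight timesteps averaged.
#' @slot template geometry for export.
#' @seealso [aggregateFields()], [exportOutputs()]
#' @export
setClass("AggregatedOutputs",
  representation(objectShade = "matrix", terrainShade = "matrix",
                 totalShade = "matrix", energy = "matrix", mode = "character",
                 units = "character", windowStart = "POSIXct",
                 windowEnd = "POSIXct", nDaylight = "integer",
                 template = "GridRaster")
)

#' CalibrationParams: the three calibration multipliers
#'
#' \code{csCali} scales clear-sky incident energy (absorbing atmospheric
#' losses), \code{trCali} multiplies every object transmittance uniformly,
#' and \code{grCali} scales terrain shade. All are nominally in (0, 1];
#' values above 1 are accepted with a warning because the peak-matching
#' update can produce them when the model under-predicts.
#'
#' @slot csCali clear-sky multiplier (default 1).
#' @slot trCali transmittance multiplier (default 1).
#' @slot grCali terrain-shade multiplier (default 0.5).
#' @seealso [CalibrationParams()], [calibrationWorkflow()]
#' @export
setClass("CalibrationParams",
  representation(csCali = "numeric", trCali = "numeric", grCali = "numeric")
)

setValidity("CalibrationParams", function(object) {
  msg <- character()
  for (nm in c("csCali", "trCali", "grCali")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, sprintf("%s must be a single finite value >= 0", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Construct CalibrationParams
#'
#' @param csCali,trCali,grCali calibration multipliers; defaults are the
#'   initial-run settings (1, 1, 0.5).
#' @return a [CalibrationParams-class] object; values above 1 trigger a
#'   warning but are not rejected.
#' @examples
#' CalibrationParams(csCali = 0.94, trCali = 0.945, grCali = 0.2)
#' @export
CalibrationParams <- function(csCali = 1, trCali = 1, grCali = 0.5) {
  for (nm in c("csCali", "trCali", "grCali")) {
    v <- get(nm)
    if (is.finite(v) && v > 1)
      warning(sprintf("%s = %g exceeds 1; accepted, but nominal range is (0, 1]",
                      nm, v))
  }
  new("CalibrationParams", csCali = as.numeric(csCali),
      trCali = as.numeric(trCali), grCali = as.numeric(grCali))
}

#' FitStats: goodness-of-fit between simulated and observed series
#'
#' @slot percentAgreement sum(observed) / sum(simulated).
#' @slot meanError mean(simulated - observed), signed, in the series' units.
#' @slot rmse root-mean-square of (simulated - observed).
#' @slot n number of compared timesteps.
#' @seealso [fitStatistics()]
#' @export
setClass("FitStats",
  representation(percentAgreement = "numeric", meanError = "numeric",
                 rmse = "numeric", n = "integer")
)

setValidity("FitStats", function(object) {
  msg <- character()
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (object@rmse < 0) msg <- c(msg, "rmse must be >= 0")
  if (object@rmse + 1e-9 < abs(object@meanError))
    msg <- c(msg, "rmse cannot be smaller than |meanError|")
  if (length(msg)) msg else TRUE
})
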