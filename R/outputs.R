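# Composition of per-timestep shade/energy grids, temporal aggregation,
# unit conversion, and raster export.

#' Compose shade and energy grids for one timestep
#'
#' Object shade is 1 - objectLight; the surviving light fraction is
#' objectLight * (1 - terrainShade); total shade is its complement; and
#' ground-level energy is the light fraction times the timestep's incident
#' clear-sky energy. On the shade scale 0 is no shade and 1 complete shade,
#' so an unshaded cell keeps its full energy.
#'
#' @param objectLight matrix of accumulated object light fractions.
#' @param terrainShade matrix of terrain shade fractions.
#' @param sun the timestep's [SunState-class].
#' @param template a [GridRaster-class] supplying geometry.
#' @param isNight logical night flag.
#' @return a [ShadeFields-class].
#' @examples
#' tpl <- GridRaster(matrix(0, 1, 1), cellsize = 10)
#' sun <- new("SunState", timestamp = Sys.time(), azimuth = 180,
#'            altitude = 90, EI = 1000, EIcos = 1000)
#' composeShadeEnergy(matrix(0.8), matrix(0.25), sun, tpl)
#' @export
composeShadeEnergy <- function(objectLight, terrainShade, sun, template,
                               isNight = FALSE) {
  if (!identical(dim(objectLight), dim(terrainShade)))
    stop("objectLight and terrainShade grids are not co-registered")
  if (!identical(dim(objectLight), dim(template)))
    stop("grids are not co-registered with the template geometry")
  light <- objectLight * (1 - terrainShade)
  energy <- light * if (isNight) 0 else sun@EIcos
  new("ShadeFields",
      objectLight = objectLight, objectShade = 1 - objectLight,
      terrainShade = terrainShade, totalShade = 1 - light,
      energy = energy, sun = sun, isNight = isNight, template = template)
}

#' Aggregate a sequence of timesteps
#'
#' Shade grids are averaged over daylight timesteps only (shade is undefined
#' without incident light); a window entirely at night yields all-NA shade
#' grids. Energy is either the mean power over every timestep of the window
#' (nights contributing zero, W/m2) or the accumulated energy (sum of power
#' times the timestep duration, J/m2).
#'
#' @param fields list of [ShadeFields-class] covering one window.
#' @param mode "mean" or "accumulated".
#' @param grainSeconds timestep duration in seconds (required for
#'   accumulated mode).
#' @param units label recorded on the result ("W" or "PAR").
#' @return an [AggregatedOutputs-class].
#' @export
aggregateFields <- function(fields, mode = c("mean", "accumulated"),
                            grainSeconds = NULL, units = "W") {
  mode <- match.arg(mode)
  if (!length(fields)) stop("empty aggregation window")
  if (mode == "accumulated" && is.null(grainSeconds))
    stop("accumulated mode requires grainSeconds")
  day <- !vapply(fields, function(f) f@isNight, logical(1L))
  d <- dim(fields[[1L]]@energy)
  meanOf <- function(name, which) {
    if (!any(which)) return(matrix(NA_real_, d[1L], d[2L]))
    Reduce(`+`, lapply(fields[which], slot, name)) / sum(which)
  }
  objectShade <- meanOf("objectShade", day)
  terrainShade <- meanOf("terrainShade", day)
  totalShade <- meanOf("totalShade", day)
  energySum <- Reduce(`+`, lapply(fields, slot, "energy"))
  energy <- if (mode == "mean") energySum / length(fields)
            else energySum * grainSeconds
  times <- as.POSIXct(vapply(fields, function(f)
    as.numeric(f@sun@timestamp), numeric(1L)), origin = "1970-01-01",
    tz = "UTC")
  new("AggregatedOutputs",
      objectShade = objectShade, terrainShade = terrainShade,
      totalShade = totalShade, energy = energy, mode = mode,
      units = units, windowStart = min(times), windowEnd = max(times),
      nDaylight = sum(day), template = fields[[1L]]@template)
}

#' Convert energy units between shortwave power and PAR photon flux
#'
#' Multiplies W/m2 by a configurable factor (default 2.02 umol s-1 W-1, a
#' generalized full-spectrum-shortwave to PAR photon-flux conversion) or
#' divides for the inverse direction.
#'
#' @param x numeric vector or matrix of energy values.
#' @param factor conversion factor, umol s-1 W-1 (> 0).
#' @param inverse if TRUE, convert PAR back to W/m2.
#' @return converted values.
#' @examples
#' convertEnergyUnits(100) # 202 umol/m2/s
#' @export
convertEnergyUnits <- function(x, factor = 2.02, inverse = FALSE) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("conversion factor must be a single value > 0")
  if (inverse) x / factor else x * factor
}

#' Export aggregated grids as ESRI ASCII rasters
#'
#' Writes one raster per requested layer with a deterministic name of the
#' form \code{<prefix>_<layer>_<window start>.asc}; re-running the export
#' overwrites byte-identically.
#'
#' @param agg an [AggregatedOutputs-class].
#' @param which subset of \code{c("energy", "total-shade", "object-shade",
#'   "terrain-shade")}.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param decimals decimal places written.
#' @return character vector of file paths, invisibly.
#' @export
exportOutputs <- function(agg, which = c("energy", "total-shade",
                                         "object-shade", "terrain-shade"),
                          dir = ".", prefix = "shadewalk", decimals = 4L) {
  which <- match.arg(which, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grids <- list(`energy` = agg@energy, `total-shade` = agg@totalShade,
                `object-shade` = agg@objectShade,
                `terrain-shade` = agg@terrainShade)
  stamp <- format(agg@windowStart, "%Y%m%d_%H%M")
  tpl <- agg@template
  paths <- character()
  for (layer in which) {
    g <- GridRaster(grids[[layer]], cellsize = tpl@cellsize,
                    xllcorner = tpl@xllcorner, yllcorner = tpl@yllcorner,
                    nodata = tpl@nodata)
    path <- file.path(dir, sprintf("%s_%s_%s.asc", prefix,
                                   gsub("-", "_", layer), stamp))
    writeAsciiGrid(g, path, decimals = decimals)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write a probe-cell time series
#'
#' Tab-separated text with one row per timestep: timestamp, energy, total
#' shade, object shade, terrain shade at the given cell.
#'
#' @param fields list of [ShadeFields-class].
#' @param probe integer \code{c(row, col)}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProbeSeries <- function(fields, probe, path) {
  rows <- vapply(fields, function(f) c(
    energy = f@energy[probe[1L], probe[2L]],
    totalShade = f@totalShade[probe[1L], probe[2L]],
    objectShade = f@objectShade[probe[1L], probe[2L]],
    terrainShade = f@terrainShade[probe[1L], probe[2L]]), numeric(4L))
  df <- data.frame(
    timestamp = vapply(fields, function(f)
      format(f@sun@timestamp, "%Y-%m-%dT%H:%M:%S"), character(1L)),
    t(rows), check.names = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
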