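# Configuration-driven simulation runs: validation, timestep iteration,
# aggregation windows, export, and logging.

.configDefaults <- function() list(
  dem = NULL, ndsm = NULL, otm = NULL,
  understory_height = NULL, understory_otm = NULL, mask = NULL,
  latitude = NULL, longitude = NULL, utc_offset = 0,
  year = NULL, start_day = NULL, stop_day = NULL, stop_year = NULL,
  daily_grain = 60, aggregation = "daily",
  start_time = NULL, stop_time = NULL,
  cs_cali = 1, tr_cali = 1, gr_cali = 0.5,
  cloud_fraction = 0,
  outputs = c("energy", "total-shade", "object-shade", "terrain-shade"),
  units = "W", par_factor = 2.02, energy_mode = "mean",
  v = NULL, probe = NULL, sensor_height = 0,
  out_dir = ".", prefix = "shadewalk", decimals = 4, seed = NULL
)

#' Read a run configuration file
#'
#' YAML key/value file mirroring the arguments of [runSimulation()]; keys
#' absent from the file take their defaults. Raster layers are given as
#' file paths to ESRI ASCII grids.
#'
#' @param path YAML file path.
#' @return a validated configuration list of class \code{RunConfig}.
#' @seealso [runSimulation()]
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  validateRunConfig(user)
}

#' Validate a run configuration
#'
#' Fills defaults and checks all invariants (temporal grain 1-1440 minutes,
#' aggregation an integer multiple of the grain, start before stop, lat/lon
#' ranges, referenced files existing) before any computation starts.
#'
#' @param config named list of configuration values.
#' @return the completed configuration, classed \code{RunConfig}.
#' @export
validateRunConfig <- function(config) {
  cfg <- .configDefaults()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  for (req in c("latitude", "longitude", "year", "start_day", "stop_day"))
    if (is.null(cfg[[req]])) stop("missing required configuration key: ", req)
  if (abs(cfg$latitude) > 90) stop("latitude must lie in [-90, 90]")
  if (abs(cfg$longitude) > 180) stop("longitude must lie in [-180, 180]")
  if (cfg$daily_grain < 1 || cfg$daily_grain > 1440)
    stop("daily_grain must lie in [1, 1440] minutes")
  if (!identical(cfg$aggregation, "daily")) {
    if (!is.numeric(cfg$aggregation) ||
        cfg$aggregation %% cfg$daily_grain != 0)
      stop("aggregation must be 'daily' or an integer multiple of daily_grain")
  }
  if (is.null(cfg$stop_year)) cfg$stop_year <- cfg$year
  start <- as.Date(cfg$start_day - 1, origin = as.Date(sprintf("%d-01-01",
                                                               cfg$year)))
  stop_ <- as.Date(cfg$stop_day - 1, origin = as.Date(sprintf("%d-01-01",
                                                              cfg$stop_year)))
  if (start > stop_) stop("start day/year must not be after stop day/year")
  cfg$.startDate <- start
  cfg$.stopDate <- stop_
  if (is.null(cfg$dem) && is.null(cfg$ndsm))
    stop("at least one of dem, ndsm must be configured")
  for (layer in c("dem", "ndsm", "otm", "understory_height",
                  "understory_otm", "mask")) {
    val <- cfg[[layer]]
    if (is.character(val) && !file.exists(val))
      stop("configured ", layer, " file not found: ", val)
  }
  if (any(cfg$cloud_fraction < 0 | cfg$cloud_fraction > 1))
    stop("cloud_fraction must lie in [0, 1]")
  if (!cfg$units %in% c("W", "PAR")) stop("units must be 'W' or 'PAR'")
  if (!cfg$energy_mode %in% c("mean", "accumulated"))
    stop("energy_mode must be 'mean' or 'accumulated'")
  class(cfg) <- c("RunConfig", "list")
  cfg
}

.loadLayer <- function(x) {
  if (is.null(x)) return(NULL)
  if (is(x, "GridRaster")) return(x)
  readAsciiGrid(x)
}

.parseClock <- function(x) {
  if (is.null(x)) return(NULL)
  parts <- as.numeric(strsplit(as.character(x), ":")[[1L]])
  parts[1L] * 60 + if (length(parts) > 1L) parts[2L] else 0
}

#' Run a configured simulation
#'
#' Iterates timesteps from the configured start to stop day at the daily
#' grain, simulating shade and energy per timestep (night steps contribute
#' zero energy without walking), aggregates per window, converts units if
#' requested, writes the selected output rasters, an optional probe-cell
#' time series, and a run log. Identical configuration and inputs produce
#' byte-identical outputs.
#'
#' @param config a \code{RunConfig} list (see [validateRunConfig()]) or the
#'   path to a YAML configuration file. Raster layers may be file paths or
#'   in-memory [GridRaster-class] objects.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with \code{outputs} (exported raster paths),
#'   \code{probe} (probe series path or NULL), \code{log} (log path) and
#'   \code{windows} (number of aggregation windows).
#' @export
runSimulation <- function(config, quiet = TRUE) {
  if (is.character(config)) config <- readRunConfig(config)
  if (!inherits(config, "RunConfig")) config <- validateRunConfig(config)
  cfg <- config

  stack <- LandscapeStack(
    dem = .loadLayer(cfg$dem), ndsm = .loadLayer(cfg$ndsm),
    otm = .loadLayer(cfg$otm),
    understoryHeight = .loadLayer(cfg$understory_height),
    understoryOtm = .loadLayer(cfg$understory_otm),
    mask = .loadLayer(cfg$mask))
  ctx <- SolarContext(cfg$latitude, cfg$longitude, cfg$utc_offset)
  params <- suppressWarnings(
    CalibrationParams(cfg$cs_cali, cfg$tr_cali, cfg$gr_cali))

  days <- seq(cfg$.startDate, cfg$.stopDate, by = "day")
  startMin <- .parseClock(cfg$start_time)
  stopMin <- .parseClock(cfg$stop_time)
  if (is.null(startMin)) startMin <- 0
  if (is.null(stopMin)) stopMin <- 1440
  grain <- cfg$daily_grain
  nSteps <- ceiling((stopMin - startMin) / grain)
  stepsPerDay <- startMin + grain * (seq_len(nSteps) - 1L)

  cloudFor <- function(i) {
    cf <- cfg$cloud_fraction
    if (length(cf) == 1L) cf else cf[((i - 1L) %% length(cf)) + 1L]
  }

  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  logPath <- file.path(cfg$out_dir, paste0(cfg$prefix, "_run.log"))
  logLines <- c(
    sprintf("run started for %s .. %s, grain %d min, aggregation %s",
            days[1L], days[length(days)], grain,
            paste(cfg$aggregation, collapse = "")),
    sprintf("site lat %.6f lon %.6f utc offset %g", cfg$latitude,
            cfg$longitude, cfg$utc_offset),
    sprintf("calibration cs %.4g tr %.4g gr %.4g; units %s; v %s",
            params@csCali, params@trCali, params@grCali, cfg$units,
            if (is.null(cfg$v)) "default (cellsize/4)" else cfg$v))

  allPaths <- character()
  probeFields <- list()
  nWindows <- 0L
  for (i in seq_along(days)) {
    dayFields <- list()
    for (m in stepsPerDay) {
      t <- as.POSIXct(paste(days[i], "00:00:00"), tz = "UTC") + m * 60
      sun <- sunState(ctx, t, params, cloudFor(i))
      dayFields[[length(dayFields) + 1L]] <-
        simulateTimestep(stack, sun, params, v = cfg$v)
    }
    if (!is.null(cfg$probe)) probeFields <- c(probeFields, dayFields)

    windows <- if (identical(cfg$aggregation, "daily"))
      list(seq_along(dayFields))
    else {
      per <- cfg$aggregation / grain
      split(seq_along(dayFields),
            (seq_along(dayFields) - 1L) %/% per)
    }
    for (w in windows) {
      agg <- aggregateFields(dayFields[w], mode = cfg$energy_mode,
                             grainSeconds = grain * 60, units = cfg$units)
      if (cfg$units == "PAR")
        agg@energy <- convertEnergyUnits(agg@energy, cfg$par_factor)
      paths <- exportOutputs(agg, which = cfg$outputs, dir = cfg$out_dir,
                             prefix = cfg$prefix, decimals = cfg$decimals)
      allPaths <- c(allPaths, paths)
      nWindows <- nWindows + 1L
      logLines <- c(logLines, sprintf(
        "window %s: %d daylight steps, mean energy %.3f",
        format(agg@windowStart, "%Y-%m-%d %H:%M"), agg@nDaylight,
        mean(agg@energy, na.rm = TRUE)))
      if (!quiet) message(logLines[length(logLines)])
    }
  }

  probePath <- NULL
  if (!is.null(cfg$probe)) {
    probePath <- file.path(cfg$out_dir, paste0(cfg$prefix, "_probe.tsv"))
    writeProbeSeries(probeFields, cfg$probe, probePath)
  }
  con <- file(logPath, "wb")
  writeLines(logLines, con)
  close(con)
  invisible(list(outputs = allPaths, probe = probePath, log = logPath,
                 windows = nWindows))
}
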