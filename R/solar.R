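# Solar geometry: declination, equation of time, hour angle, azimuth/altitude,
# top-of-atmosphere clear-sky irradiance, and the cosine-corrected incident
# energy used by the shade engine.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Day of year from a timestamp
#' @param time POSIXct (or coercible); local civil time.
#' @return integer day-of-year, 1-366.
#' @export
dayOfYear <- function(time) as.POSIXlt(time)$yday + 1L

#' Solar declination (degrees)
#'
#' Standard 23.45-degree sine model over the day of year.
#' @param n day of year, 1-366.
#' @return declination in degrees, within [-23.45, 23.45].
#' @export
solarDeclination <- function(n) 23.45 * sin(2 * pi * (284 + n) / 365)

#' Equation of time (minutes)
#'
#' Spencer's Fourier form; the difference between apparent solar time and
#' mean clock time.
#' @param n day of year.
#' @return minutes to add to mean time to obtain solar time.
#' @export
equationOfTime <- function(n) {
  g <- 2 * pi * (n - 1) / 365
  229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
            0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
}

# hour angle in degrees (0 at solar noon, negative morning) for civil times
.hourAngle <- function(ctx, time) {
  lt <- as.POSIXlt(time)
  clockMin <- lt$hour * 60 + lt$min + lt$sec / 60
  n <- dayOfYear(time)
  # longitude correction: 4 minutes per degree offset from the zone meridian
  tst <- clockMin + 4 * (ctx@longitude - 15 * ctx@utcOffset) +
    equationOfTime(n)
  (tst / 60 - 12) * 15
}

#' Solar position (azimuth and altitude)
#'
#' Altitude from the spherical-astronomy relation
#' \eqn{\gamma = \arcsin(\cos\phi\cos\delta\cos\Omega + \sin\phi\sin\delta)}
#' and azimuth from the matching horizontal direction components via the
#' two-argument arctangent, returned on the 0-360 degrees
#' clockwise-from-north convention. The hour angle is derived from civil
#' clock time using the site longitude, the UTC offset and the equation of
#' time. Vectorized over \code{time}.
#'
#' @param ctx a [SolarContext-class].
#' @param time POSIXct civil timestamps (interpreted in the context's UTC
#'   offset regardless of their formal timezone attribute).
#' @return data.frame with columns \code{azimuth} and \code{altitude}
#'   (degrees).
#' @examples
#' ctx <- SolarContext(45, 0, 0)
#' solarPosition(ctx, as.POSIXct("2008-06-21 12:00", tz = "UTC"))
#' @export
solarPosition <- function(ctx, time) {
  stopifnot(is(ctx, "SolarContext"))
  validObject(ctx)
  n <- dayOfYear(time)
  dec <- .deg2rad(solarDeclination(n))
  phi <- .deg2rad(ctx@latitude)
  om <- .deg2rad(.hourAngle(ctx, time))
  sinAlt <- cos(phi) * cos(dec) * cos(om) + sin(phi) * sin(dec)
  alt <- asin(pmin(1, pmax(-1, sinAlt)))
  az <- atan2(sin(om), cos(om) * sin(phi) - tan(dec) * cos(phi))
  az <- (180 + .rad2deg(az)) %% 360
  data.frame(azimuth = az, altitude = .rad2deg(alt))
}

#' Civil clock time of solar noon
#'
#' @param ctx a [SolarContext-class].
#' @param date a Date (or string) naming the day.
#' @return POSIXct of the local-clock instant at which the hour angle is
#'   zero.
#' @export
solarNoon <- function(ctx, date) {
  d <- as.POSIXct(paste(as.Date(date), "12:00:00"), tz = "UTC")
  n <- dayOfYear(d)
  offset <- 4 * (ctx@longitude - 15 * ctx@utcOffset) + equationOfTime(n)
  d - offset * 60
}

#' Top-of-atmosphere clear-sky irradiance
#'
#' Earth-sun distance (orbital eccentricity) correction of the solar
#' constant: \eqn{EI = S (1 + 0.034 \cos(2\pi n / 365.25))}, peaking near
#' perihelion in early January.
#'
#' @param ctx a [SolarContext-class] (supplies the solar constant), or a
#'   numeric solar constant.
#' @param n day of year, 1-366.
#' @return irradiance in W/m2.
#' @examples
#' round(clearSkyIrradiance(SolarContext(45, 0), 3))
#' @export
clearSkyIrradiance <- function(ctx, n) {
  s <- if (is(ctx, "SolarContext")) ctx@solarConstant else as.numeric(ctx)
  if (any(n < 1 | n > 366)) stop("day of year must lie in [1, 366]")
  s * (1 + 0.034 * cos(2 * pi * n / 365.25))
}

#' Cosine-corrected, calibrated incident clear-sky energy
#'
#' Projects the top-of-atmosphere irradiance onto a horizontal surface via
#' the solar zenith angle (factor \eqn{\sin(\gamma)} for altitude
#' \eqn{\gamma}), applies the clear-sky calibration multiplier and an
#' optional flat daily cloud-cover reduction, and floors the result at zero.
#' The sun at or below the horizon yields exactly zero.
#'
#' @param EI top-of-atmosphere irradiance, W/m2 (>= 0).
#' @param altitude solar altitude, degrees.
#' @param csCali clear-sky calibration multiplier.
#' @param cloudFraction daily cloud cover in [0, 1]; applied as a flat
#'   (1 - cloud) multiplier.
#' @return incident energy, W/m2.
#' @examples
#' incidentClearSky(1400, 30) # 700
#' @export
incidentClearSky <- function(EI, altitude, csCali = 1, cloudFraction = 0) {
  if (any(EI < 0)) stop("EI must be >= 0")
  if (any(cloudFraction < 0 | cloudFraction > 1))
    stop("cloudFraction must lie in [0, 1]")
  out <- sin(.deg2rad(altitude)) * EI * csCali * (1 - cloudFraction)
  out[altitude <= 0] <- 0
  pmax(out, 0)
}

#' Build the SunState of one timestep
#'
#' @param ctx a [SolarContext-class].
#' @param time POSIXct civil timestamp.
#' @param params a [CalibrationParams-class] (supplies csCali).
#' @param cloudFraction daily cloud cover in [0, 1].
#' @return a [SunState-class].
#' @export
sunState <- function(ctx, time, params = CalibrationParams(),
                     cloudFraction = 0) {
  pos <- solarPosition(ctx, time)
  EI <- clearSkyIrradiance(ctx, dayOfYear(time))
  EIcos <- incidentClearSky(EI, pos$altitude, params@csCali, cloudFraction)
  new("SunState", timestamp = as.POSIXct(time), azimuth = pos$azimuth,
      altitude = pos$altitude, EI = EI, EIcos = EIcos)
}

#' Compare the implemented solar position against an independent ephemeris
#'
#' Computes hourly (or caller-supplied) azimuth/altitude series with both
#' [solarPosition()] and the independently implemented [solarPositionMeeus()]
#' ephemeris, restricted to timestamps where both place the sun above the
#' horizon, and reports the squared Pearson correlation of each series.
#'
#' @param ctx a [SolarContext-class].
#' @param times POSIXct timestamps (default: the 24 hours of \code{date}).
#' @param date convenience: a Date used when \code{times} is missing.
#' @return list with \code{azimuthR2}, \code{altitudeR2}, \code{n}, and the
#'   aligned \code{series} data.frame.
#' @export
validateSolarPositions <- function(ctx, times = NULL, date = NULL) {
  if (is.null(times)) {
    if (is.null(date)) stop("supply times or date")
    times <- as.POSIXct(paste(as.Date(date), sprintf("%02d:00:00", 0:23)),
                        tz = "UTC")
  }
  model <- solarPosition(ctx, times)
  oracle <- solarPositionMeeus(times, ctx@latitude, ctx@longitude,
                               ctx@utcOffset)
  keep <- model$altitude > 0 & oracle$altitude > 0
  if (sum(keep) < 3L) stop("fewer than 3 daylight timestamps to compare")
  r2 <- function(a, b) stats::cor(a, b)^2
  series <- data.frame(time = times[keep],
                       azimuth = model$azimuth[keep],
                       altitude = model$altitude[keep],
                       azimuthRef = oracle$azimuth[keep],
                       altitudeRef = oracle$altitude[keep])
  list(azimuthR2 = r2(series$azimuth, series$azimuthRef),
       altitudeR2 = r2(series$altitude, series$altitudeRef),
       n = nrow(series), series = series)
}
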