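# Independent solar ephemeris (Meeus, Astronomical Algorithms, low-accuracy
# solar theory). Deliberately a separate code path from solarPosition():
# Julian centuries, geometric mean longitude/anomaly, equation of center,
# obliquity, right ascension/declination, and sidereal time, rather than
# the day-of-year declination + equation-of-time route. Used as the
# validation oracle for the solar-geometry module.

#' Independent ephemeris: solar azimuth and altitude (Meeus low-accuracy)
#'
#' @param time POSIXct civil timestamps.
#' @param latitude degrees north.
#' @param longitude degrees east-positive.
#' @param utcOffset hours ahead of UTC of the civil clock.
#' @return data.frame with \code{azimuth} (degrees clockwise from north) and
#'   \code{altitude} (degrees).
#' @seealso [validateSolarPositions()]
#' @export
solarPositionMeeus <- function(time, latitude, longitude, utcOffset = 0) {
  d2r <- pi / 180
  ut <- as.POSIXlt(as.POSIXct(time) - utcOffset * 3600)
  y <- ut$year + 1900
  m <- ut$mon + 1
  day <- ut$mday + (ut$hour + ut$min / 60 + ut$sec / 3600) / 24
  lo <- m <= 2
  y[lo] <- y[lo] - 1
  m[lo] <- m[lo] + 12
  a <- floor(y / 100)
  b <- 2 - a + floor(a / 4)
  jd <- floor(365.25 * (y + 4716)) + floor(30.6001 * (m + 1)) + day + b - 1524.5
  t <- (jd - 2451545) / 36525

  L0 <- (280.46646 + 36000.76983 * t + 0.0003032 * t^2) %% 360
  M <- (357.52911 + 35999.05029 * t - 0.0001537 * t^2) %% 360
  C <- (1.914602 - 0.004817 * t - 0.000014 * t^2) * sin(M * d2r) +
    (0.019993 - 0.000101 * t) * sin(2 * M * d2r) +
    0.000289 * sin(3 * M * d2r)
  trueLong <- (L0 + C) %% 360
  eps <- 23.43929111 - 0.0130042 * t - 1.64e-7 * t^2

  ra <- atan2(cos(eps * d2r) * sin(trueLong * d2r), cos(trueLong * d2r)) / d2r
  dec <- asin(sin(eps * d2r) * sin(trueLong * d2r)) / d2r

  gmst <- (280.46061837 + 360.98564736629 * (jd - 2451545) +
             0.000387933 * t^2) %% 360
  H <- (gmst + longitude - ra) %% 360
  H[H > 180] <- H[H > 180] - 360

  phi <- latitude * d2r
  sinAlt <- sin(phi) * sin(dec * d2r) + cos(phi) * cos(dec * d2r) * cos(H * d2r)
  alt <- asin(pmin(1, pmax(-1, sinAlt))) / d2r
  az <- atan2(sin(H * d2r),
              cos(H * d2r) * sin(phi) - tan(dec * d2r) * cos(phi)) / d2r
  az <- (az + 180) %% 360
  data.frame(azimuth = az, altitude = alt)
}
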