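# Shared helpers: tiny constructive landscapes and sun states.

gridOf <- function(m, cellsize = 10, ...) GridRaster(m, cellsize = cellsize, ...)

# 1 x 16 row of 10 m cells with a 20 m, OT 0.4 object at column 7
blockRowStack <- function() {
  ndsm <- matrix(0, 1, 16); ndsm[1, 7] <- 20
  otm <- matrix(1, 1, 16); otm[1, 7] <- 0.4
  LandscapeStack(dem = gridOf(matrix(0, 1, 16)), ndsm = gridOf(ndsm),
                 otm = gridOf(otm))
}

# 1 x 16 row with a 30 m terrain wall at column 8
ridgeRowStack <- function() {
  dem <- matrix(0, 1, 16); dem[1, 8] <- 30
  LandscapeStack(dem = gridOf(dem))
}

fakeSun <- function(azimuth, altitude, EI = 1400, EIcos = NULL) {
  if (is.null(EIcos))
    EIcos <- if (altitude > 0) sin(altitude * pi / 180) * EI else 0
  new("SunState", timestamp = as.POSIXct("2008-07-06 12:00", tz = "UTC"),
      azimuth = azimuth, altitude = altitude, EI = EI, EIcos = EIcos)
}

# rotate a matrix 90 degrees clockwise (north edge becomes east edge)
rotateCW <- function(m) t(m[nrow(m):1, , drop = FALSE])

rotateStackCW <- function(stack) {
  rot <- function(l) if (is.null(l)) NULL else
    GridRaster(rotateCW(gridValues(l)), cellsize = cellSize(l))
  LandscapeStack(dem = rot(stackLayer(stack, "dem")),
                 ndsm = rot(stackLayer(stack, "ndsm")),
                 otm = rot(stackLayer(stack, "otm")))
}

# calibration-recovery landscape: random canopy plus a bare 25 m terrain
# wall three cells east of the open probe cell (10, 8)
recoveryStack <- function() {
  st0 <- makeFixture("random-canopy", nrows = 20, ncols = 20, cellsize = 10,
                     density = 0.35, seed = 99)
  dem <- gridValues(stackLayer(st0, "dem")); dem[, 11] <- 25
  nd <- gridValues(stackLayer(st0, "ndsm")); nd[, 11] <- 0; nd[10, 8] <- 0
  ot <- gridValues(stackLayer(st0, "otm")); ot[, 11] <- 1; ot[10, 8] <- 1
  LandscapeStack(dem = gridOf(dem), ndsm = gridOf(nd), otm = gridOf(ot))
}

hourlyTimes <- function(days, hours = 0:23) {
  sort(as.POSIXct(outer(days, sprintf("%02d:00:00", hours), paste),
                  tz = "UTC"))
}

# synthetic probe observations generated directly from walkCell (not via the
# calibration code path)
syntheticProbeSeries <- function(stack, ctx, times, params, probe,
                                 sensorHeight = 0) {
  vals <- vapply(times, function(t) {
    s <- sunState(ctx, t, params)
    if (s@altitude <= 0) return(0)
    r <- walkCell(stack, s, probe, params, sensorHeight = sensorHeight)
    r$objectLight * (1 - r$terrainShade) * s@EIcos
  }, numeric(1L))
  data.frame(timestamp = times, value = vals)
}
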