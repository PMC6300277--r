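# The walking algorithm: from each origin cell, march toward the sun in
# fixed-length steps, and each time a NEW cell is entered assess terrain
# interception and object transmittance at the ray height there. Walks
# terminate on terrain penetration, on leaving the data extent, or on the
# ray exceeding the precomputed ceiling. Each origin's walk is vectorized:
# all sample positions, cell indices and height tests are whole-vector
# operations.

#' Per-step displacement toward the sun
#'
#' Computed once per timestep and reused for every origin cell. The
#' continuous form run = sin(azimuth) * v (east-positive), rise =
#' cos(azimuth) * v (north-positive) covers all four quadrants of the
#' clockwise-from-north azimuth convention.
#'
#' @param azimuth degrees clockwise from north, [0, 360).
#' @param v step length in metres (> 0); defaults elsewhere to a quarter of
#'   the cell size.
#' @return list with \code{run}, \code{rise} (metres/step) and \code{v}.
#' @examples
#' stepVector(90, 1) # due east: run 1, rise 0
#' @export
stepVector <- function(azimuth, v) {
  if (v <= 0) stop("step length v must be > 0")
  if (azimuth < 0 || azimuth >= 360) stop("azimuth must lie in [0, 360)")
  a <- azimuth * pi / 180
  list(run = sin(a) * v, rise = cos(a) * v, v = v)
}

#' Solar ray height above the origin
#'
#' The vertical rise component is |tan(altitude)| times the horizontal
#' distance walked; the absolute ray height adds the origin elevation.
#'
#' @param originElevation metres.
#' @param altitude solar altitude in degrees, (0, 90].
#' @param xTotal horizontal distance from the origin, metres (>= 0).
#' @return list with \code{vrc} (vertical rise component) and \code{ah}
#'   (absolute ray height), metres.
#' @examples
#' rayHeight(100, 30, 10)$ah # 105.7735
#' @export
rayHeight <- function(originElevation, altitude, xTotal) {
  if (any(altitude <= 0))
    stop("altitude must be > 0 (night walks are skipped by the caller)")
  if (any(xTotal < 0)) stop("xTotal must be >= 0")
  vrc <- abs(tan(altitude * pi / 180)) * xTotal
  list(vrc = vrc, ah = originElevation + vrc)
}

#' Object interaction of the ray at one encountered cell
#'
#' The object delta height is the ray height minus the object top
#' (elevation + object height). Non-negative: the ray passes over and the
#' factor is 1. Negative: the ray penetrates the voxel containing the ray
#' height -- the canopy voxel (otm) at or above the understory top, the
#' understory voxel (understoryOtm) below it -- and the factor is that
#' voxel's transmittance times \code{trCali}, clamped to [0, 1] with a
#' warning if the product leaves the unit interval.
#'
#' @param solarAH absolute ray height, metres.
#' @param demElev ground elevation of the encountered cell, metres.
#' @param ndsmHeight object height above ground, metres.
#' @param otm canopy transmittance fraction.
#' @param understoryHeight,understoryOtm optional lower-voxel layer values.
#' @param trCali transmittance calibration multiplier.
#' @return multiplicative transmittance factor in [0, 1].
#' @examples
#' assessObject(25, 0, 20, 0.4)            # ray above: 1
#' assessObject(10, 0, 20, 0.4)            # penetrates canopy: 0.4
#' @export
assessObject <- function(solarAH, demElev, ndsmHeight, otm,
                         understoryHeight = NULL, understoryOtm = NULL,
                         trCali = 1) {
  odh <- solarAH - (demElev + ndsmHeight)
  if (odh >= 0) return(1)
  raw <- otm
  if (!is.null(understoryHeight) && !is.null(understoryOtm) &&
      !is.na(understoryHeight) && solarAH < demElev + understoryHeight)
    raw <- understoryOtm
  fac <- raw * trCali
  if (is.na(fac)) return(1) # missing transmittance: transparent
  if (fac < 0 || fac > 1) {
    warning(sprintf("transmittance factor %g outside [0, 1]; clamped", fac))
    fac <- min(max(fac, 0), 1)
  }
  fac
}

#' Terrain interaction of the ray at one encountered cell
#'
#' @param solarAH absolute ray height, metres.
#' @param demElev ground elevation, metres.
#' @return \code{"penetrated"} if the ray is strictly below the ground
#'   (terrain delta height < 0, terminating the walk), else \code{"above"};
#'   an exact tie counts as above.
#' @examples
#' assessTerrain(12, 30) # "penetrated"
#' @export
assessTerrain <- function(solarAH, demElev) {
  if (solarAH - demElev < 0) "penetrated" else "above"
}

#' Terrain shade of a terrain-terminated walk
#'
#' Inverse-distance weakening: the ground calibration factor divided by the
#' number of distinct cells walked, so a wall one cell away casts maximum
#' topographic shade and distant terrain casts progressively less
#' (accounting for scattered indirect light).
#'
#' @param cellsWalked distinct cells entered before termination (>= 1).
#' @param grCali ground-effect calibration multiplier.
#' @return shade fraction in [0, 1].
#' @examples
#' terrainShadeValue(4, 0.5) # 0.125
#' @export
terrainShadeValue <- function(cellsWalked, grCali = 0.5) {
  if (any(cellsWalked < 1))
    stop("cellsWalked must be >= 1 when a walk terminates on terrain")
  grCali / cellsWalked
}

# Extract plain arrays/geometry from a stack once per timestep.
.stackArrays <- function(stack) {
  tpl <- .stackTemplate(stack)
  list(
    nr = tpl@nrows, nc = tpl@ncols, cs = tpl@cellsize,
    xll = tpl@xllcorner, yll = tpl@yllcorner,
    dem = if (!is.null(stack@dem)) stack@dem@values else NULL,
    ndsm = if (!is.null(stack@ndsm)) stack@ndsm@values else NULL,
    otm = if (!is.null(stack@otm)) stack@otm@values else NULL,
    uh = if (!is.null(stack@understoryHeight)) stack@understoryHeight@values
         else NULL,
    uotm = if (!is.null(stack@understoryOtm)) stack@understoryOtm@values
           else NULL,
    mask = if (!is.null(stack@mask)) stack@mask@values else NULL,
    ceiling = stack@ceiling, template = tpl
  )
}

# Vectorized single-origin walk. `arr` from .stackArrays; az/alt in degrees.
.walkRay <- function(arr, row, col, azimuth, altitude, trCali, grCali, v,
                     heightOffset = 0, detail = FALSE) {
  a <- azimuth * pi / 180
  run <- sin(a) * v
  rise <- cos(a) * v
  tanA <- tan(altitude * pi / 180)
  e0 <- if (!is.null(arr$dem)) arr$dem[row, col] else 0
  e0 <- e0 + heightOffset
  x0 <- arr$xll + (col - 0.5) * arr$cs
  y0 <- arr$yll + (arr$nr - row + 0.5) * arr$cs

  # sample count bounds: above the ceiling or past the grid diagonal the
  # walk must already have terminated
  kCeil <- if (e0 >= arr$ceiling) 1 else
    floor((arr$ceiling - e0) / (tanA * v)) + 1
  kEdgeBound <- ceiling(sqrt((arr$nc^2 + arr$nr^2)) * arr$cs / v) + 2
  K <- min(kCeil, kEdgeBound)

  k <- seq_len(K)
  xr <- (x0 + k * run - arr$xll) / arr$cs
  yr <- (y0 + k * rise - arr$yll) / arr$cs
  rx <- round(xr)
  cols <- ifelse(abs(xr - rx) < 1e-9, rx + (run > 0), floor(xr) + 1)
  ry <- round(yr)
  srow <- ifelse(abs(yr - ry) < 1e-9, ry + (rise > 0), floor(yr) + 1)
  rows <- arr$nr - srow + 1

  inGrid <- cols >= 1 & cols <= arr$nc & rows >= 1 & rows <= arr$nr
  firstOut <- which(!inGrid)[1L]
  kEdge <- if (is.na(firstOut)) Inf else firstOut
  byCeiling <- kCeil <= kEdge
  noTerrainTerm <- if (byCeiling) "ceiling" else "edge"

  # include the first out-of-grid sample: the ray may cross one final
  # in-grid cell between the last inside sample and the exit point
  kMaxAssess <- min(kEdge, K)
  out <- list(objectLight = 1, terrainShade = 0, cellsWalked = 0L,
              terminatedBy = noTerrainTerm)
  if (detail) out$penetrated <- numeric()
  if (kMaxAssess < 1) return(out)

  ks <- seq_len(kMaxAssess)
  ids <- (srow[ks] + 1) * (arr$nc + 3) + cols[ks] # unique also off-grid
  originId <- (arr$nr - row + 2) * (arr$nc + 3) + col
  isNew <- ids != c(originId, ids[-length(ids)])
  if (!any(isNew)) return(out)
  entryK <- ks[isNew]
  ecol <- cols[entryK]
  esrow <- srow[entryK]

  # exact horizontal distance at which the ray crosses into each new cell:
  # the later of the x- and y-edge crossings between the previous cell and
  # this one (samples only detect the entry; the entry distance itself is
  # geometric, so the assessed ray height does not depend on v). When a
  # step changes both row and column the ray traversed an intermediate
  # cell between the two samples; it is inserted so every crossed cell is
  # assessed, with the rare exact corner pass going diagonally.
  prevCol <- c(col, cols[ks])[entryK]
  prevSrow <- c(arr$nr - row + 1, srow[ks])[entryK]
  dxU <- sin(a)
  dyU <- cos(a)
  nE0 <- length(entryK)
  sx <- rep(-Inf, nE0)
  chx <- ecol != prevCol
  if (any(chx)) {
    edgeX <- arr$xll + arr$cs * (if (run > 0) ecol[chx] - 1 else ecol[chx])
    sx[chx] <- (edgeX - x0) / dxU
  }
  sy <- rep(-Inf, nE0)
  chy <- esrow != prevSrow
  if (any(chy)) {
    edgeY <- arr$yll + arr$cs * (if (rise > 0) esrow[chy] - 1 else esrow[chy])
    sy[chy] <- (edgeY - y0) / dyU
  }
  sMain <- pmax(sx, sy)
  both <- chx & chy & abs(sx - sy) > 1e-9
  xFirst <- sx < sy
  interSrow <- ifelse(xFirst, prevSrow, esrow)
  interCol <- ifelse(xFirst, ecol, prevCol)
  interS <- pmin(sx, sy)
  candSrow <- as.vector(rbind(interSrow, esrow))
  candCol <- as.vector(rbind(interCol, ecol))
  candS <- as.vector(rbind(interS, sMain))
  candK <- as.vector(rbind(entryK, entryK))
  keepC <- as.vector(rbind(both, rep(TRUE, nE0)))
  esrow <- candSrow[keepC]
  ecol <- candCol[keepC]
  entryK <- candK[keepC]
  sEntry <- pmin(pmax(candS[keepC], (entryK - 1) * v), entryK * v)
  inG <- ecol >= 1 & ecol <= arr$nc & esrow >= 1 & esrow <= arr$nr
  esrow <- esrow[inG]
  ecol <- ecol[inG]
  sEntry <- sEntry[inG]
  if (!length(sEntry)) return(out)
  erow <- arr$nr - esrow + 1
  AH <- e0 + tanA * sEntry

  # ceiling termination: stop before the first entry above the ceiling
  over <- which(AH > arr$ceiling + 1e-9)[1L]
  if (!is.na(over)) {
    if (over == 1L) return(out)
    keep <- seq_len(over - 1L)
    erow <- erow[keep]; ecol <- ecol[keep]
    AH <- AH[keep]
  }
  nE <- length(AH)

  demE <- if (!is.null(arr$dem)) arr$dem[cbind(erow, ecol)] else
    rep(0, nE)
  iTerr <- NA_integer_
  if (!is.null(arr$dem)) {
    pen <- !is.na(demE) & (demE - AH > 1e-9)
    iTerr <- which(pen)[1L]
  }
  terrain <- !is.na(iTerr)
  nObj <- if (terrain) iTerr - 1L else nE

  OLD <- 1
  rawPen <- numeric()
  if (!is.null(arr$ndsm) && nObj >= 1L) {
    ix <- seq_len(nObj)
    nd <- arr$ndsm[cbind(erow[ix], ecol[ix])]
    ground <- demE[ix]
    grounded <- !is.na(ground)
    consider <- grounded & !is.na(nd) & nd > 0
    top <- ground + nd
    hit <- consider & (AH[ix] - top < -1e-9)
    if (any(hit)) {
      raw <- arr$otm[cbind(erow[ix], ecol[ix])]
      if (!is.null(arr$uh) && !is.null(arr$uotm)) {
        uh <- arr$uh[cbind(erow[ix], ecol[ix])]
        under <- hit & !is.na(uh) & (AH[ix] < ground + uh)
        raw[under] <- arr$uotm[cbind(erow[ix], ecol[ix])][under]
      }
      raw <- raw[hit]
      raw[is.na(raw)] <- 1
      fac <- pmin(pmax(raw * trCali, 0), 1)
      OLD <- prod(fac)
      rawPen <- raw
    }
  }

  out$objectLight <- OLD
  if (terrain) {
    out$terrainShade <- min(1, grCali / iTerr)
    out$cellsWalked <- iTerr
    out$terminatedBy <- "terrain"
  } else {
    out$cellsWalked <- nE
  }
  if (detail) out$penetrated <- rawPen
  out
}

#' Walk one origin cell toward the sun
#'
#' Marches from the origin's cell centre at the origin's ground elevation
#' (plus an optional sensor height) in steps of \code{v}; every distinct new
#' cell entered is assessed for terrain interception and, on non-terminating
#' cells, object transmittance. The origin's own object never shades itself.
#' Sample points landing exactly on a cell edge belong to the cell ahead in
#' the walk direction; a terrain tie (ray height equal to ground) does not
#' terminate.
#'
#' @param stack a [LandscapeStack-class].
#' @param sun a [SunState-class], or a list with \code{azimuth} and
#'   \code{altitude} in degrees (altitude must be > 0).
#' @param origin integer \code{c(row, col)} (row 1 = north).
#' @param params a [CalibrationParams-class].
#' @param v step length in metres; default cellsize / 4.
#' @param sensorHeight metres added to the origin elevation (e.g. a PAR
#'   sensor mounted above ground).
#' @param detail if TRUE, also return the raw transmittances of penetrated
#'   voxels (used by the calibration workflow).
#' @return list with \code{objectLight} (accumulated light fraction),
#'   \code{terrainShade}, \code{cellsWalked}, \code{terminatedBy} (one of
#'   "terrain", "edge", "ceiling"), and optionally \code{penetrated}.
#' @examples
#' stack <- makeFixture("flat", nrows = 4, ncols = 8, cellsize = 10)
#' walkCell(stack, list(azimuth = 90, altitude = 30), c(2, 2))
#' @export
walkCell <- function(stack, sun, origin, params = CalibrationParams(),
                     v = NULL, sensorHeight = 0, detail = FALSE) {
  arr <- .stackArrays(stack)
  az <- if (is(sun, "SunState")) sun@azimuth else sun$azimuth
  alt <- if (is(sun, "SunState")) sun@altitude else sun$altitude
  if (alt <= 0) stop("sun altitude must be > 0 (night timesteps are skipped)")
  if (is.null(v)) v <- arr$cs / 4
  if (v <= 0) stop("step length v must be > 0")
  row <- origin[1L]
  col <- origin[2L]
  if (row < 1 || row > arr$nr || col < 1 || col > arr$nc)
    stop("origin outside the grid")
  if (!is.null(arr$dem) && is.na(arr$dem[row, col]))
    stop("origin is a nodata cell")
  if (!is.null(arr$mask) &&
      (is.na(arr$mask[row, col]) || arr$mask[row, col] <= 0))
    stop("origin is outside the area-of-interest mask")
  .walkRay(arr, row, col, az, alt, params@trCali, params@grCali, v,
           heightOffset = sensorHeight, detail = detail)
}

#' Simulate one timestep over the whole landscape
#'
#' Applies the walking algorithm to every eligible origin cell (non-nodata
#' and, when a mask is present, inside the mask; masked-out and nodata cells
#' still cast shade during other cells' walks) and composes the shade and
#' energy grids. Night timesteps (altitude <= 0) skip all walks and yield
#' object light 1, terrain shade 0 and energy 0, flagged for aggregation.
#'
#' @param stack a [LandscapeStack-class].
#' @param sun a [SunState-class].
#' @param params a [CalibrationParams-class].
#' @param v step length in metres; default cellsize / 4.
#' @return a [ShadeFields-class].
#' @examples
#' stack <- makeFixture("block", nrows = 4, ncols = 8, cellsize = 10,
#'                      height = 20, transmittance = 0.4)
#' ctx <- SolarContext(45, -120, -8)
#' sun <- sunState(ctx, as.POSIXct("2008-07-06 10:00", tz = "UTC"))
#' fields <- simulateTimestep(stack, sun)
#' @export
simulateTimestep <- function(stack, sun, params = CalibrationParams(),
                             v = NULL) {
  stopifnot(is(stack, "LandscapeStack"), is(sun, "SunState"))
  arr <- .stackArrays(stack)
  if (is.null(v)) v <- arr$cs / 4
  eligible <- if (!is.null(arr$dem)) !is.na(arr$dem) else !is.na(arr$ndsm)
  if (!is.null(arr$mask))
    eligible <- eligible & !is.na(arr$mask) & arr$mask > 0

  OL <- matrix(NA_real_, arr$nr, arr$nc)
  TS <- matrix(NA_real_, arr$nr, arr$nc)
  if (sun@altitude <= 0) {
    OL[eligible] <- 1
    TS[eligible] <- 0
    return(composeShadeEnergy(OL, TS, sun, arr$template, isNight = TRUE))
  }
  idx <- which(eligible)
  if (length(idx)) {
    rc <- arrayInd(idx, c(arr$nr, arr$nc))
    for (i in seq_along(idx)) {
      res <- .walkRay(arr, rc[i, 1L], rc[i, 2L], sun@azimuth, sun@altitude,
                      params@trCali, params@grCali, v)
      OL[idx[i]] <- res$objectLight
      TS[idx[i]] <- res$terrainShade
    }
  }
  composeShadeEnergy(OL, TS, sun, arr$template, isNight = FALSE)
}
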