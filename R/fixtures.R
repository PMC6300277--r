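# Synthetic landscape generators and the independent brute-force ray-march
# oracle used to validate the walking algorithm.

# Local RNG scope: draws are reproducible from `seed` and never disturb the
# caller's global random state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate a synthetic test landscape
#'
#' Deterministic fixture landscapes for testing and demonstration:
#' \describe{
#'   \item{flat}{uniform elevation, no objects.}
#'   \item{block}{flat terrain with a single object cell (or the cell at
#'     \code{position}) of the given height and transmittance.}
#'   \item{ridge}{flat terrain with one full row or column raised to
#'     \code{height} (pure topography, no objects).}
#'   \item{slope}{elevation increasing by \code{gradient} metres per cell
#'     eastward.}
#'   \item{random-canopy}{flat terrain with a random canopy: each cell
#'     carries an object with probability \code{density}, heights and
#'     transmittances drawn uniformly from \code{heightRange} and
#'     \code{otRange} under \code{seed}.}
#' }
#'
#' @param kind fixture kind, see above.
#' @param nrows,ncols grid dimensions.
#' @param cellsize cell edge length, metres.
#' @param elevation base elevation, metres.
#' @param height object/ridge height, metres.
#' @param transmittance object transmittance fraction.
#' @param position \code{c(row, col)} of the block or the ridge line index;
#'   default centre.
#' @param orientation ridge orientation, "ns" (a column) or "ew" (a row).
#' @param gradient slope rise per cell, metres.
#' @param density canopy cover fraction for random-canopy.
#' @param heightRange,otRange uniform draw ranges for random-canopy.
#' @param seed integer seed for random-canopy (identical seed, identical
#'   landscape).
#' @return a [LandscapeStack-class].
#' @examples
#' makeFixture("block", nrows = 5, ncols = 9, cellsize = 10, height = 20,
#'             transmittance = 0.4)
#' @export
makeFixture <- function(kind = c("flat", "block", "ridge", "slope",
                                 "random-canopy"),
                        nrows = 20, ncols = 20, cellsize = 10,
                        elevation = 0, height = 20, transmittance = 0.4,
                        position = NULL, orientation = c("ns", "ew"),
                        gradient = 1, density = 0.3,
                        heightRange = c(5, 25), otRange = c(0.2, 0.8),
                        seed = NULL) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  dem <- matrix(elevation, nrows, ncols)
  mk <- function(m) GridRaster(m, cellsize = cellsize)
  if (kind == "flat") {
    return(LandscapeStack(dem = mk(dem)))
  }
  if (kind == "block") {
    if (is.null(position))
      position <- c(ceiling(nrows / 2), ceiling(ncols / 2))
    ndsm <- matrix(0, nrows, ncols)
    otm <- matrix(1, nrows, ncols)
    ndsm[position[1L], position[2L]] <- height
    otm[position[1L], position[2L]] <- transmittance
    return(LandscapeStack(dem = mk(dem), ndsm = mk(ndsm), otm = mk(otm)))
  }
  if (kind == "ridge") {
    if (is.null(position))
      position <- if (orientation == "ns") ceiling(ncols / 2)
                  else ceiling(nrows / 2)
    if (orientation == "ns") dem[, position] <- elevation + height
    else dem[position, ] <- elevation + height
    return(LandscapeStack(dem = mk(dem)))
  }
  if (kind == "slope") {
    dem <- dem + gradient * (col(dem) - 1)
    return(LandscapeStack(dem = mk(dem)))
  }
  # random-canopy
  .withSeed(seed, {
    canopy <- matrix(stats::runif(nrows * ncols) < density, nrows, ncols)
    h <- matrix(stats::runif(nrows * ncols, heightRange[1L], heightRange[2L]),
                nrows, ncols)
    ot <- matrix(stats::runif(nrows * ncols, otRange[1L], otRange[2L]),
                 nrows, ncols)
    ndsm <- ifelse(canopy, h, 0)
    otm <- ifelse(canopy, ot, 1)
    LandscapeStack(dem = mk(dem), ndsm = mk(ndsm), otm = mk(otm))
  })
}

#' Brute-force fine-step light-transport oracle
#'
#' Marches a 3-D point from the origin cell centre along the exact sun
#' direction vector at a fine step (default cellsize / 50), with no rise/run
#' caching and no quarter-cell discretization: per distinct cell whose
#' column the point crosses, the cell's transmittance is applied once if any
#' sample inside the cell lies below the object top, and the walk records a
#' terrain hit at the first cell where a sample drops below the ground
#' surface. Implemented independently of the walking algorithm (plain floor
#' cell indexing, per-sample height tests) so that agreement between the two
#' is evidence rather than tautology.
#'
#' @param stack a [LandscapeStack-class].
#' @param azimuth,altitude sun direction, degrees (altitude > 0).
#' @param origin integer \code{c(row, col)}.
#' @param step horizontal march step in metres, much smaller than the cell
#'   size.
#' @param trCali transmittance multiplier applied to encountered voxels.
#' @param sensorHeight metres added to the start height.
#' @return list with \code{objectLight}, \code{terrainHit} (logical),
#'   \code{cellsToTerrain} (distinct cells entered up to and including the
#'   terrain cell, or NA), and \code{terminatedBy}.
#' @export
bruteForceLightFraction <- function(stack, azimuth, altitude, origin,
                                    step = NULL, trCali = 1,
                                    sensorHeight = 0) {
  stopifnot(is(stack, "LandscapeStack"))
  if (altitude <= 0) stop("altitude must be > 0")
  tpl <- .stackTemplate(stack)
  cs <- tpl@cellsize
  if (is.null(step)) step <- cs / 50
  if (step <= 0) stop("step must be > 0")
  nr <- tpl@nrows
  nc <- tpl@ncols
  dem <- if (!is.null(stack@dem)) stack@dem@values else matrix(0, nr, nc)
  ndsm <- if (!is.null(stack@ndsm)) stack@ndsm@values else NULL
  otm <- if (!is.null(stack@otm)) stack@otm@values else NULL
  uh <- if (!is.null(stack@understoryHeight)) stack@understoryHeight@values
        else NULL
  uotm <- if (!is.null(stack@understoryOtm)) stack@understoryOtm@values
          else NULL

  a <- azimuth * pi / 180
  dx <- sin(a)
  dy <- cos(a)
  slope <- tan(altitude * pi / 180)
  row0 <- origin[1L]
  col0 <- origin[2L]
  z0 <- dem[row0, col0]
  if (is.na(z0)) z0 <- 0
  z0 <- z0 + sensorHeight
  x0 <- tpl@xllcorner + (col0 - 0.5) * cs
  y0 <- tpl@yllcorner + (nr - row0 + 0.5) * cs

  sCeil <- if (z0 >= stack@ceiling) step else
    (stack@ceiling - z0) / slope + step
  sEdge <- sqrt((nc * cs)^2 + (nr * cs)^2) + 2 * step
  sMax <- min(sCeil, sEdge)
  s <- seq(step, sMax, by = step)
  xs <- x0 + s * dx
  ys <- y0 + s * dy
  zs <- z0 + s * slope

  cols <- floor((xs - tpl@xllcorner) / cs) + 1
  srow <- floor((ys - tpl@yllcorner) / cs) + 1
  rows <- nr - srow + 1
  inGrid <- cols >= 1 & cols <= nc & rows >= 1 & rows <= nr
  firstOut <- which(!inGrid)[1L]
  ceilHit <- zs > stack@ceiling
  firstCeil <- which(ceilHit)[1L]
  cut <- min(firstOut, firstCeil, length(s) + 1L, na.rm = TRUE) - 1L
  terminated <- if (!is.na(firstCeil) && (is.na(firstOut) ||
                                          firstCeil <= firstOut)) "ceiling"
                else "edge"
  out <- list(objectLight = 1, terrainHit = FALSE,
              cellsToTerrain = NA_integer_, terminatedBy = terminated)
  if (cut < 1L) return(out)

  keep <- seq_len(cut)
  rows <- rows[keep]; cols <- cols[keep]; zs <- zs[keep]
  ids <- (rows - 1) * nc + cols
  originId <- (row0 - 1) * nc + col0
  notOrigin <- ids != originId
  if (!any(notOrigin)) return(out)
  rows <- rows[notOrigin]; cols <- cols[notOrigin]; zs <- zs[notOrigin]
  ids <- ids[notOrigin]

  grp <- cumsum(ids != c(-1, ids[-length(ids)]))
  demS <- dem[cbind(rows, cols)]
  below <- !is.na(demS) & (zs < demS)
  firstBelow <- which(below)[1L]
  if (!is.na(firstBelow)) {
    terrGrp <- grp[firstBelow]
    out$terrainHit <- TRUE
    out$cellsToTerrain <- as.integer(terrGrp)
    out$terminatedBy <- "terrain"
    keepObj <- grp < terrGrp # the terminating cell's object is not applied
  } else {
    keepObj <- rep(TRUE, length(grp))
  }

  if (!is.null(ndsm) && any(keepObj)) {
    g0 <- ifelse(is.na(demS), NA_real_, demS)
    nd <- ndsm[cbind(rows, cols)]
    top <- g0 + nd
    inVox <- keepObj & !is.na(top) & !is.na(nd) & nd > 0 & zs < top
    if (any(inVox)) {
      hitGrp <- unique(grp[inVox])
      fac <- vapply(hitGrp, function(g) {
        i <- which(inVox & grp == g)[1L]
        raw <- otm[rows[i], cols[i]]
        if (!is.null(uh) && !is.null(uotm)) {
          u <- uh[rows[i], cols[i]]
          if (!is.na(u) && zs[i] < g0[i] + u) raw <- uotm[rows[i], cols[i]]
        }
        if (is.na(raw)) 1 else min(max(raw * trCali, 0), 1)
      }, numeric(1L))
      out$objectLight <- prod(fac)
    }
  }
  out
}
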