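# ESRI ASCII Grid reading/writing and landscape stack assembly.

.geometryMismatch <- function(a, b, tol = 1e-6) {
  bad <- character()
  if (a@ncols != b@ncols) bad <- c(bad, "ncols")
  if (a@nrows != b@nrows) bad <- c(bad, "nrows")
  if (abs(a@cellsize - b@cellsize) > tol) bad <- c(bad, "cellsize")
  if (abs(a@xllcorner - b@xllcorner) > tol) bad <- c(bad, "xllcorner")
  if (abs(a@yllcorner - b@yllcorner) > tol) bad <- c(bad, "yllcorner")
  bad
}

#' Read an ESRI ASCII Grid raster
#'
#' Parses the 5-6 line header (case-insensitive keys; both the
#' \code{xllcorner}/\code{yllcorner} and \code{xllcenter}/\code{yllcenter}
#' dialects are accepted, center coordinates being converted to corner form)
#' followed by \code{nrows x ncols} whitespace-separated values in top-down
#' row order. Cells equal to the nodata sentinel become \code{NA}; a missing
#' \code{NODATA_value} header defaults the sentinel to -9999.
#'
#' @param path path to a \code{.asc} file.
#' @return a [GridRaster-class].
#' @examples
#' f <- tempfile(fileext = ".asc")
#' writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
#'              "cellsize 10", "NODATA_value -9999", "1 2", "3 4"), f)
#' gridValues(readAsciiGrid(f))
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  head <- readLines(path, n = 6L)
  hdr <- list()
  nHeader <- 0L
  keys <- c("ncols", "nrows", "xllcorner", "xllcenter", "yllcorner",
            "yllcenter", "cellsize", "nodata_value")
  for (line in head) {
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) >= 2L && tolower(tok[1L]) %in% keys) {
      val <- suppressWarnings(as.numeric(tok[2L]))
      if (is.na(val))
        stop("malformed header line (non-numeric value): '", line, "'")
      hdr[[tolower(tok[1L])]] <- val
      nHeader <- nHeader + 1L
    } else break
  }
  for (req in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[req]]))
      stop("malformed header: missing required key '", req, "'")
  if (is.null(hdr$xllcorner) && is.null(hdr$xllcenter))
    stop("malformed header: missing xllcorner/xllcenter")
  if (is.null(hdr$yllcorner) && is.null(hdr$yllcenter))
    stop("malformed header: missing yllcorner/yllcenter")
  if (hdr$cellsize <= 0)
    stop("malformed header: cellsize must be > 0 (got ", hdr$cellsize, ")")
  if (hdr$ncols < 1 || hdr$nrows < 1 || hdr$ncols != round(hdr$ncols) ||
      hdr$nrows != round(hdr$nrows))
    stop("malformed header: ncols and nrows must be positive integers")
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    hdr$yllcenter - hdr$cellsize / 2
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999

  raw <- scan(path, what = character(), skip = nHeader, quiet = TRUE)
  vals <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(vals) & !(toupper(raw) %in% c("NA", "NAN")))
  if (length(bad))
    stop(sprintf("non-numeric token '%s' at value position %d", raw[bad[1L]],
                 bad[1L]))
  expected <- as.integer(hdr$nrows) * as.integer(hdr$ncols)
  if (length(vals) != expected)
    stop(sprintf("cell count mismatch: %d values read, %d expected (%d x %d)",
                 length(vals), expected, hdr$nrows, hdr$ncols))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  GridRaster(m, cellsize = hdr$cellsize, xllcorner = xll, yllcorner = yll,
             nodata = nodata)
}

#' Write a GridRaster as an ESRI ASCII Grid
#'
#' Always writes the corner-form header so round-trips are deterministic.
#' \code{NA} cells are written as the nodata sentinel verbatim (not formatted
#' to \code{decimals}).
#'
#' @param grid a [GridRaster-class].
#' @param path output path.
#' @param decimals number of decimal places for data values.
#' @return \code{path}, invisibly.
#' @export
writeAsciiGrid <- function(grid, path, decimals = 6L) {
  stopifnot(is(grid, "GridRaster"))
  validObject(grid)
  fmtNum <- function(x) {
    # header numbers: plain decimal, no trailing zeros beyond need
    s <- format(x, scientific = FALSE, trim = TRUE)
    s
  }
  hdr <- c(
    paste("ncols", grid@ncols),
    paste("nrows", grid@nrows),
    paste("xllcorner", fmtNum(grid@xllcorner)),
    paste("yllcorner", fmtNum(grid@yllcorner)),
    paste("cellsize", fmtNum(grid@cellsize)),
    paste("NODATA_value", fmtNum(grid@nodata))
  )
  v <- grid@values
  tok <- formatC(v, format = "f", digits = as.integer(decimals))
  tok[is.na(v)] <- fmtNum(grid@nodata)
  body <- apply(matrix(tok, nrow = grid@nrows), 1L, paste, collapse = " ")
  con <- file(path, "wb") # binary mode: byte-identical output on re-export
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

# first non-NULL layer, used as the geometry template of a stack
.stackTemplate <- function(stack) {
  for (nm in c("dem", "ndsm", "otm", "understoryHeight", "understoryOtm",
               "mask")) {
    l <- slot(stack, nm)
    if (!is.null(l)) return(l)
  }
  stop("stack has no layers")
}

#' Assemble a co-registered landscape stack
#'
#' Validates that every supplied layer shares identical geometry, that
#' transmittance values lie in [0, 1], and precomputes the walk ceiling: the
#' maximum over non-missing cells of elevation plus object height (a missing
#' layer contributing zero). With only a DEM the simulation runs in
#' topographic-only mode; with only an nDSM + OTM in object-only mode.
#'
#' @param dem elevation layer ([GridRaster-class], metres), optional.
#' @param ndsm object-height layer (metres above ground), optional; requires
#'   \code{otm}.
#' @param otm object transmittance layer (fraction 0-1).
#' @param understoryHeight,understoryOtm optional second (lower) voxel layer:
#'   below \code{understoryHeight} the understory transmittance applies,
#'   above it (up to the ndsm top) the canopy transmittance applies.
#' @param mask optional 0/1 layer restricting which cells are walk origins;
#'   cells outside the mask still cast shade.
#' @return a validated [LandscapeStack-class].
#' @examples
#' dem <- GridRaster(matrix(0, 5, 5), cellsize = 10)
#' LandscapeStack(dem = dem)
#' @export
LandscapeStack <- function(dem = NULL, ndsm = NULL, otm = NULL,
                           understoryHeight = NULL, understoryOtm = NULL,
                           mask = NULL) {
  if (is.null(dem) && is.null(ndsm))
    stop("at least one of dem, ndsm must be provided")
  if (!is.null(ndsm) && is.null(otm))
    stop("otm must be provided whenever ndsm is provided")
  tpl <- if (!is.null(dem)) dem else ndsm
  layers <- list(dem = dem, ndsm = ndsm, otm = otm,
                 understoryHeight = understoryHeight,
                 understoryOtm = understoryOtm, mask = mask)
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (is.null(l)) next
    bad <- .geometryMismatch(tpl, l)
    if (length(bad))
      stop(sprintf("layer '%s' is not co-registered: %s differ",
                   nm, paste(bad, collapse = ", ")))
  }
  d <- if (!is.null(dem)) dem@values else
    matrix(0, tpl@nrows, tpl@ncols)
  h <- if (!is.null(ndsm)) ndsm@values else
    matrix(0, tpl@nrows, tpl@ncols)
  d0 <- ifelse(is.na(d), 0, d)
  h0 <- ifelse(is.na(h), 0, h)
  ceiling <- max(d0 + h0)
  obj <- new("LandscapeStack", dem = dem, ndsm = ndsm, otm = otm,
             understoryHeight = understoryHeight,
             understoryOtm = understoryOtm, mask = mask,
             ceiling = ceiling)
  validObject(obj)
  obj
}
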