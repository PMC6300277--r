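writeAsc <- function(lines) {
  f <- tempfile(fileext = ".asc")
  writeLines(lines, f)
  f
}

test_that("ascii grids parse with header, nodata default, and both corner dialects", {
  f <- writeAsc(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
                  "cellsize 10", "NODATA_value -9999", "1 2", "3 4"))
  g <- readAsciiGrid(f)
  expect_identical(gridValues(g), matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(cellSize(g), 10)
  expect_equal(noDataValue(g), -9999)

  # missing NODATA_value header defaults the sentinel
  f2 <- writeAsc(c("NCOLS 2", "NROWS 1", "xllcorner 5", "yllcorner 5",
                   "cellsize 2", "7 -9999"))
  g2 <- readAsciiGrid(f2)
  expect_equal(noDataValue(g2), -9999)
  expect_true(is.na(gridValues(g2)[1, 2]))

  # center dialect converts to corner form
  f3 <- writeAsc(c("ncols 2", "nrows 2", "xllcenter 5", "yllcenter 5",
                   "cellsize 10", "1 2", "3 4"))
  g3 <- readAsciiGrid(f3)
  expect_equal(g3@xllcorner, 0)
  expect_equal(g3@yllcorner, 0)
})

test_that("malformed grids fail with informative errors", {
  f <- writeAsc(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
                  "cellsize 10", "1 2 3"))
  expect_error(readAsciiGrid(f), "3 values read, 4 expected")

  f2 <- writeAsc(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
                   "cellsize 0", "1 2", "3 4"))
  expect_error(readAsciiGrid(f2), "cellsize must be > 0")

  f3 <- writeAsc(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
                   "cellsize 10", "1 2", "3 four"))
  expect_error(readAsciiGrid(f3), "non-numeric token 'four' at value position 4")

  f4 <- writeAsc(c("ncols 2", "nrows 2", "cellsize 10", "1 2", "3 4"))
  expect_error(readAsciiGrid(f4), "xllcorner")
})

test_that("write/read round-trips preserve header exactly and values to precision", {
  m <- matrix(c(1.23456789, -2.5, NA, 0.123456), 2, 2)
  g <- GridRaster(m, cellsize = 7.5, xllcorner = 100.25, yllcorner = -30,
                  nodata = -1234)
  f <- tempfile(fileext = ".asc")
  writeAsciiGrid(g, f, decimals = 3)
  # formatting contract: 0.123456 at 3 decimals becomes the token 0.123
  expect_true(any(grepl("\\b0\\.123\\b", readLines(f))))
  # sentinel written verbatim, not formatted as data
  body <- readLines(f)[-(1:6)]
  expect_true(any(grepl("(^| )-1234( |$)", body)))
  g2 <- readAsciiGrid(f)
  expect_equal(g2@xllcorner, g@xllcorner)
  expect_equal(g2@yllcorner, g@yllcorner)
  expect_equal(g2@cellsize, g@cellsize)
  expect_equal(g2@nodata, g@nodata)
  expect_equal(gridValues(g2), round(gridValues(g), 3))

  # higher precision round-trips the fixture grids exactly enough
  st <- makeFixture("random-canopy", nrows = 6, ncols = 6, seed = 3)
  otm <- stackLayer(st, "otm")
  f2 <- tempfile(fileext = ".asc")
  writeAsciiGrid(otm, f2, decimals = 10)
  expect_equal(gridValues(readAsciiGrid(f2)), gridValues(otm),
               tolerance = 1e-9)
})

test_that("stack assembly validates co-registration, domains, and layer rules", {
  dem <- gridOf(matrix(0, 4, 4))
  ndsm <- gridOf(matrix(5, 4, 4))
  otm <- gridOf(matrix(0.5, 4, 4))

  expect_error(LandscapeStack(ndsm = ndsm), "otm must be provided")
  expect_error(LandscapeStack(), "at least one of dem, ndsm")

  shifted <- GridRaster(matrix(0, 4, 4), cellsize = 10, xllcorner = 5)
  expect_error(LandscapeStack(dem = dem, ndsm = shifted,
                              otm = otm), "xllcorner")
  wrongSize <- gridOf(matrix(0, 3, 4))
  expect_error(LandscapeStack(dem = dem, ndsm = wrongSize, otm = otm),
               "nrows")

  badOtm <- gridOf(matrix(c(1.2, rep(0.5, 15)), 4, 4))
  expect_error(LandscapeStack(dem = dem, ndsm = ndsm, otm = badOtm),
               "\\[0, 1\\].*cell \\(1, 1\\)")

  # dem-only topographic mode is allowed
  expect_s4_class(LandscapeStack(dem = dem), "LandscapeStack")
})

test_that("ceiling is the cell-wise max of dem + ndsm", {
  dem <- matrix(0, 3, 3); dem[1, 1] <- 100; dem[2, 2] <- 50
  ndsm <- matrix(0, 3, 3); ndsm[2, 2] <- 30
  st <- LandscapeStack(dem = gridOf(dem), ndsm = gridOf(ndsm),
                       otm = gridOf(matrix(1, 3, 3)))
  expect_equal(stackCeiling(st), 100) # not 130: max is cell-wise
  ndsm[1, 1] <- 5
  st2 <- LandscapeStack(dem = gridOf(dem), ndsm = gridOf(ndsm),
                        otm = gridOf(matrix(1, 3, 3)))
  expect_equal(stackCeiling(st2), 105)
})

test_that("stack construction is idempotent and order-insensitive in optionals", {
  dem <- gridOf(matrix(1, 4, 4))
  ndsm <- gridOf(matrix(2, 4, 4))
  otm <- gridOf(matrix(0.7, 4, 4))
  mask <- gridOf(matrix(1, 4, 4))
  a <- LandscapeStack(dem = dem, ndsm = ndsm, otm = otm, mask = mask)
  b <- LandscapeStack(mask = mask, otm = otm, ndsm = ndsm, dem = dem)
  expect_equal(a, b)
  # rebuilding from the same layers changes nothing
  c_ <- LandscapeStack(dem = stackLayer(a, "dem"),
                       ndsm = stackLayer(a, "ndsm"),
                       otm = stackLayer(a, "otm"),
                       mask = stackLayer(a, "mask"))
  expect_equal(a, c_)
})
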