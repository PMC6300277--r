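writeFixtureRasters <- function(dir) {
  st <- makeFixture("block", nrows = 6, ncols = 8, cellsize = 10,
                    height = 20, transmittance = 0.4)
  paths <- list(dem = file.path(dir, "dem.asc"),
                ndsm = file.path(dir, "ndsm.asc"),
                otm = file.path(dir, "otm.asc"))
  writeAsciiGrid(stackLayer(st, "dem"), paths$dem)
  writeAsciiGrid(stackLayer(st, "ndsm"), paths$ndsm)
  writeAsciiGrid(stackLayer(st, "otm"), paths$otm)
  paths
}

baseConfig <- function(paths, out) {
  list(dem = paths$dem, ndsm = paths$ndsm, otm = paths$otm,
       latitude = 44.916, longitude = -123.001, utc_offset = -8,
       year = 2008, start_day = 188, stop_day = 188, daily_grain = 60,
       aggregation = "daily", outputs = "energy", out_dir = out,
       probe = c(3, 2))
}

test_that("configuration validation catches the contract violations", {
  d <- tempfile(); dir.create(d)
  paths <- writeFixtureRasters(d)
  cfg <- baseConfig(paths, file.path(d, "out"))

  bad <- cfg; bad$daily_grain <- 30; bad$aggregation <- 45
  expect_error(validateRunConfig(bad), "multiple of daily_grain")
  bad <- cfg; bad$latitude <- 95
  expect_error(validateRunConfig(bad), "latitude")
  bad <- cfg; bad$start_day <- 200
  expect_error(validateRunConfig(bad), "start day")
  bad <- cfg; bad$dem <- file.path(d, "missing.asc")
  expect_error(validateRunConfig(bad), "missing.asc")
  bad <- cfg; bad$frobnicate <- 1
  expect_error(validateRunConfig(bad), "unknown configuration keys")
  bad <- cfg; bad$daily_grain <- 0
  expect_error(validateRunConfig(bad), "daily_grain")
  expect_s3_class(validateRunConfig(cfg), "RunConfig")
})

test_that("yaml configs round-trip through the reader", {
  d <- tempfile(); dir.create(d)
  paths <- writeFixtureRasters(d)
  yml <- file.path(d, "run.yaml")
  writeLines(c(
    sprintf("dem: %s", paths$dem), sprintf("ndsm: %s", paths$ndsm),
    sprintf("otm: %s", paths$otm),
    "latitude: 44.916", "longitude: -123.001", "utc_offset: -8",
    "year: 2008", "start_day: 188", "stop_day: 188",
    "daily_grain: 120", "aggregation: daily",
    sprintf("out_dir: %s", file.path(d, "out"))), yml)
  cfg <- readRunConfig(yml)
  expect_equal(cfg$daily_grain, 120)
  expect_equal(cfg$latitude, 44.916)
})

test_that("a one-day run produces outputs, a probe series, and a log", {
  d <- tempfile(); dir.create(d)
  flat <- file.path(d, "flat.asc")
  writeAsciiGrid(stackLayer(makeFixture("flat", nrows = 6, ncols = 8), "dem"),
                 flat)
  cfg <- baseConfig(list(dem = flat), file.path(d, "out"))
  cfg$ndsm <- NULL
  cfg$otm <- NULL
  res <- runSimulation(cfg)
  expect_equal(res$windows, 1L)
  expect_true(all(file.exists(res$outputs)))
  expect_true(file.exists(res$probe))
  expect_true(file.exists(res$log))

  # daily-mean energy curve: daylight probe energy tracks sin(altitude)
  probe <- utils::read.table(res$probe, sep = "\t", header = TRUE)
  expect_equal(nrow(probe), 24L)
  ctx <- SolarContext(44.916, -123.001, -8)
  alt <- solarPosition(ctx, as.POSIXct(probe$timestamp, tz = "UTC",
                                       format = "%Y-%m-%dT%H:%M:%S"))$altitude
  day <- alt > 0
  expect_gt(stats::cor(probe$energy[day], sin(alt[day] * pi / 180)), 0.999)
  expect_true(all(probe$energy[!day] == 0))
})

test_that("identical configurations produce byte-identical outputs", {
  d <- tempfile(); dir.create(d)
  paths <- writeFixtureRasters(d)
  out1 <- file.path(d, "out1"); out2 <- file.path(d, "out2")
  cfg1 <- baseConfig(paths, out1)
  cfg2 <- baseConfig(paths, out2)
  r1 <- runSimulation(cfg1)
  r2 <- runSimulation(cfg2)
  b1 <- readBin(r1$outputs[1L], "raw", file.size(r1$outputs[1L]))
  b2 <- readBin(r2$outputs[1L], "raw", file.size(r2$outputs[1L]))
  expect_identical(b1, b2)
})

test_that("forced start/stop clock times restrict the daily window", {
  d <- tempfile(); dir.create(d)
  paths <- writeFixtureRasters(d)
  cfg <- baseConfig(paths, file.path(d, "outw"))
  cfg$start_time <- "09:00"
  cfg$stop_time <- "15:00"
  res <- runSimulation(cfg)
  probe <- utils::read.table(res$probe, sep = "\t", header = TRUE)
  expect_equal(nrow(probe), 6L)
  hours <- as.integer(substr(probe$timestamp, 12, 13))
  expect_true(all(hours >= 9 & hours < 15))
})

test_that("sub-daily aggregation and PAR units are honoured", {
  d <- tempfile(); dir.create(d)
  paths <- writeFixtureRasters(d)
  cfg <- baseConfig(paths, file.path(d, "outp"))
  cfg$aggregation <- 720
  cfg$units <- "PAR"
  cfg$probe <- NULL
  res <- runSimulation(cfg)
  expect_equal(res$windows, 2L)
  # PAR values are the W/m2 run times the conversion factor
  cfgW <- baseConfig(paths, file.path(d, "outw2"))
  cfgW$aggregation <- 720
  cfgW$probe <- NULL
  resW <- runSimulation(cfgW)
  gP <- gridValues(readAsciiGrid(res$outputs[1L]))
  gW <- gridValues(readAsciiGrid(resW$outputs[1L]))
  expect_equal(gP, round(gW * 2.02, 4), tolerance = 1e-3)
})
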