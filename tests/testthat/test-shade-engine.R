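test_that("step vector covers all quadrants of the compass convention", {
  s <- stepVector(90, 1)
  expect_equal(c(s$run, s$rise), c(1, 0))
  s <- stepVector(0, 2)
  expect_equal(c(s$run, s$rise), c(0, 2))
  s <- stepVector(225, 1)
  expect_equal(c(s$run, s$rise), c(-sqrt(2) / 2, -sqrt(2) / 2))
  # unit-length invariant
  for (az in seq(0, 350, by = 35)) {
    s <- stepVector(az, 2.5)
    expect_equal(s$run^2 + s$rise^2, 2.5^2)
  }
  expect_error(stepVector(360, 1), "azimuth")
  expect_error(stepVector(90, 0), "v must be > 0")
})

test_that("ray height follows the tangent relation", {
  expect_equal(rayHeight(0, 45, 10)$vrc, 10)
  expect_equal(rayHeight(100, 30, 10)$ah, 100 + 10 * tan(pi / 6))
  expect_equal(rayHeight(57, 60, 0)$ah, 57)
  expect_error(rayHeight(0, 0, 5), "altitude must be > 0")
})

test_that("object assessment applies the voxel sign rule and product semantics", {
  expect_equal(assessObject(25, 0, 20, 0.4), 1)       # passes over
  expect_equal(assessObject(10, 0, 20, 0.4), 0.4)     # penetrates
  expect_equal(assessObject(20, 0, 20, 0.4), 1)       # tie passes
  expect_equal(assessObject(10, 0, 20, 0.4, trCali = 0.5), 0.2)
  # understory voxel below the understory top, canopy above it
  expect_equal(assessObject(3, 0, 20, 0.4, understoryHeight = 8,
                            understoryOtm = 0.9), 0.9)
  expect_equal(assessObject(12, 0, 20, 0.4, understoryHeight = 8,
                            understoryOtm = 0.9), 0.4)
  expect_warning(f <- assessObject(10, 0, 20, 0.8, trCali = 1.5), "clamped")
  expect_equal(f, 1)
  # two successive penetrated cells multiply
  expect_equal(assessObject(10, 0, 20, 0.5) * assessObject(12, 0, 20, 0.5),
               0.25)
})

test_that("terrain assessment and inverse-distance shade follow the sign rules", {
  expect_equal(assessTerrain(12, 30), "penetrated")
  expect_equal(assessTerrain(12, 5), "above")
  expect_equal(assessTerrain(12, 12), "above") # tie does not terminate
  expect_equal(terrainShadeValue(1, 0.5), 0.5)
  expect_equal(terrainShadeValue(4, 0.5), 0.125)
  expect_lt(terrainShadeValue(1e6, 0.5), 1e-6)
  expect_error(terrainShadeValue(0, 0.5), "cellsWalked")
})

test_that("hand-derived walks reproduce the block and ridge cases exactly", {
  # object at 10 m distance, 20 m tall, OT 0.4, sun along the row at 30 deg
  r <- walkCell(blockRowStack(), list(azimuth = 90, altitude = 30), c(1, 6))
  expect_equal(r$objectLight, 0.4)
  expect_equal(r$terrainShade, 0)
  expect_false(r$terminatedBy == "terrain")

  # 30 m terrain wall two cells ahead: terminates after 2 cells, shade 0.25
  r2 <- walkCell(ridgeRowStack(), list(azimuth = 90, altitude = 30), c(1, 6))
  expect_equal(r2$terminatedBy, "terrain")
  expect_equal(r2$cellsWalked, 2L)
  expect_equal(r2$terrainShade, 0.25)
  expect_equal(r2$objectLight, 1)

  # flat landscape: nothing to intercept
  r3 <- walkCell(makeFixture("flat", nrows = 4, ncols = 8),
                 list(azimuth = 213, altitude = 47), c(2, 5))
  expect_equal(r3$objectLight, 1)
  expect_equal(r3$terrainShade, 0)
  expect_true(r3$terminatedBy %in% c("edge", "ceiling"))
})

test_that("walk preconditions are enforced", {
  st <- makeFixture("flat", nrows = 4, ncols = 4)
  expect_error(walkCell(st, list(azimuth = 90, altitude = -3), c(2, 2)),
               "altitude must be > 0")
  expect_error(walkCell(st, list(azimuth = 90, altitude = 30), c(9, 2)),
               "outside the grid")
  dem <- matrix(0, 3, 3); dem[2, 2] <- NA
  stNA <- LandscapeStack(dem = gridOf(dem))
  expect_error(walkCell(stNA, list(azimuth = 90, altitude = 30), c(2, 2)),
               "nodata")
})

test_that("object light is independent of the step length", {
  st <- blockRowStack()
  base <- walkCell(st, list(azimuth = 90, altitude = 30), c(1, 6))$objectLight
  for (v in c(10 / 4, 10 / 7, 10 / 10, 10 / 20)) {
    expect_equal(
      walkCell(st, list(azimuth = 90, altitude = 30), c(1, 6),
               v = v)$objectLight, base)
  }
  # also on a random canopy at an oblique azimuth
  stc <- makeFixture("random-canopy", nrows = 15, ncols = 15, seed = 5)
  for (v in c(10 / 4, 10 / 8, 10 / 16)) {
    expect_equal(
      walkCell(stc, list(azimuth = 197, altitude = 33), c(8, 8),
               v = v)$objectLight,
      walkCell(stc, list(azimuth = 197, altitude = 33), c(8, 8))$objectLight)
  }
})

test_that("shade is monotone in transmittance and object height", {
  sun <- list(azimuth = 238, altitude = 28)
  st <- makeFixture("random-canopy", nrows = 12, ncols = 12, seed = 21)
  otm <- gridValues(stackLayer(st, "otm"))
  ndsm <- gridValues(stackLayer(st, "ndsm"))
  dem <- stackLayer(st, "dem")
  base <- vapply(1:12, function(r)
    walkCell(st, sun, c(r, 6))$objectLight, numeric(1))

  # raising every OTM value never decreases any cell's light fraction
  up <- LandscapeStack(dem = dem, ndsm = gridOf(ndsm),
                       otm = gridOf(pmin(otm + 0.15, 1)))
  lighter <- vapply(1:12, function(r)
    walkCell(up, sun, c(r, 6))$objectLight, numeric(1))
  expect_true(all(lighter >= base - 1e-12))

  # raising every object height never increases any cell's light fraction
  taller <- LandscapeStack(dem = dem, ndsm = gridOf(ndsm * 1.5),
                           otm = gridOf(otm))
  darker <- vapply(1:12, function(r)
    walkCell(taller, sun, c(r, 6))$objectLight, numeric(1))
  expect_true(all(darker <= base + 1e-12))
})

test_that("rotating the landscape and azimuth together rotates the outputs", {
  st <- makeFixture("random-canopy", nrows = 12, ncols = 12, seed = 7)
  rot <- rotateStackCW(st)
  for (az in c(0, 90, 180, 270)) {
    f1 <- simulateTimestep(st, fakeSun(az, 35))
    f2 <- simulateTimestep(rot, fakeSun((az + 90) %% 360, 35))
    expect_equal(rotateCW(f1@objectLight), f2@objectLight)
    expect_equal(rotateCW(f1@terrainShade), f2@terrainShade)
  }
})

test_that("timestep simulation honours masks, nodata origins, and night", {
  dem <- matrix(0, 5, 5); dem[2, 2] <- NA
  mask <- matrix(0, 5, 5); mask[3, ] <- 1
  stM <- LandscapeStack(dem = gridOf(dem), mask = gridOf(mask))
  f <- simulateTimestep(stM, fakeSun(120, 40))
  expect_true(all(is.na(f@objectLight[-3, ])))
  expect_true(all(!is.na(f@objectLight[3, ])))

  # masked cells still cast shade: compare in-mask values with unmasked run
  ndsm <- matrix(0, 5, 5); ndsm[2, 3] <- 25
  otm <- matrix(1, 5, 5); otm[2, 3] <- 0.5
  stObj <- LandscapeStack(dem = gridOf(matrix(0, 5, 5)), ndsm = gridOf(ndsm),
                          otm = gridOf(otm))
  stObjM <- LandscapeStack(dem = gridOf(matrix(0, 5, 5)), ndsm = gridOf(ndsm),
                           otm = gridOf(otm), mask = gridOf(mask))
  sun <- fakeSun(0, 30) # sun due north: shadow cast south over row 3
  full <- simulateTimestep(stObj, sun)
  masked <- simulateTimestep(stObjM, sun)
  expect_equal(masked@objectLight[3, ], full@objectLight[3, ])
  expect_lt(full@objectLight[3, 3], 1) # the object really shades row 3

  # nodata origins yield nodata outputs
  stNA <- LandscapeStack(dem = gridOf(dem))
  fNA <- simulateTimestep(stNA, fakeSun(90, 45))
  expect_true(is.na(fNA@objectLight[2, 2]))
  expect_false(anyNA(fNA@objectLight[3, ]))

  # sun below horizon: night fields with zero energy
  fN <- simulateTimestep(stObj, fakeSun(15, -4))
  expect_true(fN@isNight)
  expect_true(all(fN@energy == 0))
  expect_true(all(fN@objectLight == 1))
})

test_that("cast shadows have the analytic length on flat terrain", {
  # single 20 m column on 10 m cells; altitudes chosen across the range
  st <- makeFixture("block", nrows = 21, ncols = 21, cellsize = 10,
                    height = 20, transmittance = 0.3)
  for (gamma in c(20, 40)) {
    expected <- floor(20 / tan(gamma * pi / 180) / 10)
    for (az in c(0, 90, 180, 270)) {
      a <- az * pi / 180
      dr <- round(cos(a)); dc <- round(-sin(a)) # anti-sunward axis
      shaded <- vapply(1:9, function(d)
        walkCell(st, list(azimuth = az, altitude = gamma),
                 c(11 + d * dr, 11 + d * dc))$objectLight < 1, logical(1))
      expect_equal(sum(shaded), expected)
      # shadow band carries the object transmittance, beyond it nothing
      if (expected >= 1)
        expect_equal(walkCell(st, list(azimuth = az, altitude = gamma),
                              c(11 + dr, 11 + dc))$objectLight, 0.3)
    }
  }
})

test_that("walks agree with the independent fine-step oracle", {
  set.seed(42)
  agree <- 0L
  total <- 0L
  for (i in 1:4) {
    st <- makeFixture("random-canopy", nrows = 15, ncols = 15, cellsize = 10,
                      seed = 400 + i)
    for (j in 1:2) {
      az <- runif(1, 0, 360)
      alt <- runif(1, 20, 60)
      for (r in 1:15) for (cc in 1:15) {
        e <- walkCell(st, list(azimuth = az, altitude = alt), c(r, cc))
        o <- bruteForceLightFraction(st, az, alt, c(r, cc), step = 10 / 200)
        ok <- abs(e$objectLight - o$objectLight) < 1e-9 &&
          (e$terminatedBy == "terrain") == o$terrainHit
        agree <- agree + ok
        total <- total + 1L
      }
    }
  }
  expect_gte(agree / total, 0.99)
})
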