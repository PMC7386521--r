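test_that("road rasterization marks crossed cells, fastest class wins", {
  g <- gridSpec(10, 10, cellSize = 100)
  ## horizontal PRIMARY along the centre of row 3 (y = 750)
  primary <- list(coords = cbind(c(0, 1000), c(750, 750)), class = "PRIMARY")
  rr <- rasterizeRoads(roadNetwork(list(primary)), g)
  expect_true(all(rasterValues(rr)[3, ] == 1L))
  expect_true(all(rasterValues(rr)[-3, ] == 0L))
  ## TERTIARY crossing vertically through column 5 (x = 450)
  tert <- list(coords = cbind(c(450, 450), c(0, 1000)), class = "TERTIARY")
  rr2 <- rasterizeRoads(roadNetwork(list(primary, tert)), g)
  expect_equal(rasterValues(rr2)[3, 5], 1L)  # PRIMARY beats TERTIARY
  expect_equal(rasterValues(rr2)[7, 5], 3L)
  ## empty network leaves everything untagged
  expect_true(all(rasterValues(rasterizeRoads(roadNetwork(), g)) == 0L))
  ## a segment entirely outside the grid is ignored with a warning
  far <- list(coords = cbind(c(5000, 6000), c(5000, 5000)), class = "PRIMARY")
  expect_warning(rr3 <- rasterizeRoads(roadNetwork(list(far)), g), "outside")
  expect_true(all(rasterValues(rr3) == 0L))
})

test_that("friction combines land cover, roads and the barrier rule", {
  codes <- landCoverCodes()
  g <- gridSpec(3, 3, cellSize = 100)
  lc <- matrix(codes[["BARREN"]], 3, 3)
  lc[1, 1] <- codes[["WATER"]]
  lc[2, 2] <- codes[["FOREST"]]
  lc[3, 3] <- codes[["WATER"]]
  land <- new("LandCoverRaster", grid = g, values = lc)
  road <- new("RoadClassRaster", grid = g,
              values = matrix(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L), 3, 3))
  fr <- buildFriction(land, road, defaultSpeedTable())
  v <- rasterValues(fr)
  expect_equal(v[2, 1], 5)          # barren walking speed
  expect_equal(v[2, 2], 2)          # forest walking speed
  expect_true(is.na(v[1, 1]))       # open water: barrier
  expect_true(fr@barrierMask[1, 1])
  expect_equal(v[3, 3], 100)        # road over water: bridge, not barrier
  expect_false(fr@barrierMask[3, 3])
  ## traversal time through a cell: 100 m at 5 km/h = 72 s; at 100 km/h 3.6 s
  expect_equal(0.1 / v[2, 1] * 3600, 72)
  expect_equal(0.1 / v[3, 3] * 3600, 3.6)
})

test_that("friction rejects classes the speed table does not cover", {
  land <- uniformLandCover(3, 3, "FOREST")
  noForest <- new("SpeedTable", speeds = c(BARREN = 5, PRIMARY = 100),
                  barriers = "WATER")
  expect_error(buildFriction(land, NULL, noForest), "FOREST")
})

test_that("rebuilding friction from identical inputs is bit-identical", {
  sc <- syntheticScenario(seed = 4)
  g <- gridSpec(60, 60, cellSize = 100)
  land <- generateLandscape(sc, g)
  rr <- rasterizeRoads(land$roads, g)
  f1 <- buildFriction(land$landcover, rr, defaultSpeedTable())
  f2 <- buildFriction(land$landcover, rr, defaultSpeedTable())
  expect_identical(rasterValues(f1), rasterValues(f2))
  expect_identical(f1@barrierMask, f2@barrierMask)
})

test_that("raising a class speed never increases any travel time", {
  sc <- syntheticScenario(seed = 15)
  g <- gridSpec(60, 60, cellSize = 100)
  land <- generateLandscape(sc, g)
  rr <- rasterizeRoads(land$roads, g)
  fac <- generateFacilities(sc, land$landcover)
  for (cls in c("TERTIARY", "FOREST", "BARREN")) {
    slow <- defaultSpeedTable()
    bump <- structure(slow@speeds[[cls]] * 2, names = cls)
    fast <- defaultSpeedTable(speeds = bump)
    ttSlow <- travelTimeTo(buildFriction(land$landcover, rr, slow), fac, "any")
    ttFast <- travelTimeTo(buildFriction(land$landcover, rr, fast), fac, "any")
    expect_true(all(rasterValues(ttFast) <= rasterValues(ttSlow) + 1e-9),
                info = cls)
  }
})

test_that("a road makes a cell at least as fast as without it", {
  land <- uniformLandCover(5, 5, "FOREST")
  g <- gridSpecOf(land)
  road <- list(coords = cbind(c(0, 500), c(250, 250)), class = "TERTIARY")
  rr <- rasterizeRoads(roadNetwork(list(road)), g)
  with_ <- rasterValues(buildFriction(land, rr, defaultSpeedTable()))
  without <- rasterValues(buildFriction(land, NULL, defaultSpeedTable()))
  expect_true(all(with_ >= without))
})

test_that("optional slope correction only slows walking, never roads", {
  land <- uniformLandCover(20, 20, "BARREN")
  g <- gridSpecOf(land)
  elev <- new("ElevationRaster", grid = g,
              values = outer(seq(0, 950, by = 50), rep(1, 20)))
  road <- list(coords = cbind(c(0, 2000), c(950, 950)), class = "PRIMARY")
  rr <- rasterizeRoads(roadNetwork(list(road)), g)
  flat <- buildFriction(land, rr, defaultSpeedTable())
  steep <- buildFriction(land, rr, defaultSpeedTable(), elevation = elev,
                         slopeAdjust = TRUE)
  walkCells <- rasterValues(rr) == 0L
  expect_true(all(rasterValues(steep)[walkCells] <
                    rasterValues(flat)[walkCells]))
  expect_equal(rasterValues(steep)[!walkCells],
               rasterValues(flat)[!walkCells])
  expect_error(buildFriction(land, rr, defaultSpeedTable(),
                             slopeAdjust = TRUE), "elevation")
})
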