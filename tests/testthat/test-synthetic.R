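test_that("generators are pure functions of scenario and seed", {
  sc <- syntheticScenario(seed = 42, nSettlements = 5)
  g <- gridSpec(60, 60, cellSize = 100)
  a <- generateLandscape(sc, g)
  b <- generateLandscape(sc, g)
  expect_identical(rasterValues(a$landcover), rasterValues(b$landcover))
  expect_identical(a$roads@segments, b$roads@segments)
  expect_identical(rasterValues(a$elevation), rasterValues(b$elevation))
  g1 <- coarsenGrid(g, 10)
  expect_identical(rasterValues(generatePopulation(sc, a$landcover, g1)),
                   rasterValues(generatePopulation(sc, a$landcover, g1)))
  expect_identical(facilityRecords(generateFacilities(sc, a$landcover)),
                   facilityRecords(generateFacilities(sc, a$landcover)))
  ## a different seed changes the world
  sc2 <- syntheticScenario(seed = 43, nSettlements = 5)
  expect_false(identical(rasterValues(generateLandscape(sc2, g)$landcover),
                         rasterValues(a$landcover)))
})

test_that("land cover respects requested fractions and structure", {
  g <- gridSpec(80, 80, cellSize = 100)
  dry <- syntheticScenario(seed = 7, waterFraction = 0)
  lc <- generateLandscape(dry, g)$landcover
  expect_false(any(rasterValues(lc) == landCoverCodes()[["WATER"]]))

  wet <- syntheticScenario(seed = 7, waterFraction = 0.15)
  v <- rasterValues(generateLandscape(wet, g)$landcover)
  expect_equal(mean(v == landCoverCodes()[["WATER"]]), 0.15, tolerance = 0.2)
  expect_true(all(v %in% landCoverCodes()))
})

test_that("road network is a spanning tree over the settlements", {
  g <- gridSpec(60, 60, cellSize = 100)
  for (n in c(2L, 5L, 9L)) {
    sc <- syntheticScenario(seed = 5, nSettlements = n)
    roads <- generateLandscape(sc, g)$roads
    expect_gte(length(roads@segments), n - 1L)
    expect_true(all(vapply(roads@segments, function(s) s$class,
                           "") %in% roadClasses()))
  }
})

test_that("population total is conserved and placed off water", {
  g <- gridSpec(60, 60, cellSize = 100)
  sc <- syntheticScenario(seed = 9, totalPopulation = 10000)
  land <- generateLandscape(sc, g)
  pop <- generatePopulation(sc, land$landcover, coarsenGrid(g, 10))
  expect_equal(sum(rasterValues(pop)), 10000, tolerance = 1e-9)
  ## fully-water 1 km cells carry no population
  waterBlock <- rasterValues(land$landcover) == landCoverCodes()[["WATER"]]
  full <- matrix(FALSE, 6, 6)
  for (i in 1:6) for (j in 1:6)
    full[i, j] <- all(waterBlock[(i * 10 - 9):(i * 10), (j * 10 - 9):(j * 10)])
  expect_true(all(rasterValues(pop)[full] == 0))
})

test_that("an all-water landscape cannot host population or facilities", {
  g <- gridSpec(20, 20, cellSize = 100)
  lcAllWater <- new("LandCoverRaster", grid = g,
                    values = matrix(landCoverCodes()[["WATER"]], 20, 20))
  sc <- syntheticScenario(seed = 1)
  expect_error(generatePopulation(sc, lcAllWater, coarsenGrid(g, 10)),
               "no habitable")
  expect_error(generateFacilities(sc, lcAllWater), "non-water")
})

test_that("facilities carry requested tags, stay in-extent and off water", {
  g <- gridSpec(80, 80, cellSize = 100)
  sc <- syntheticScenario(
    seed = 21,
    facilityCounts = data.frame(source = c("MFL", "OSM"),
                                type = c("hospital", "clinic"),
                                n = c(3L, 2L), stringsAsFactors = FALSE),
    duplicateFraction = 0)
  land <- generateLandscape(sc, g)
  fac <- generateFacilities(sc, land$landcover)
  r <- facilityRecords(fac)
  expect_equal(nrow(r), 5L)
  expect_equal(sum(r$source == "MFL" & r$is_hospital), 3L)
  expect_equal(sum(r$source == "OSM" & !r$is_hospital), 2L)
  ext <- gridExtent(gridSpecOf(land$landcover))
  expect_true(all(r$x >= ext["xmin"] & r$x <= ext["xmax"] &
                  r$y >= ext["ymin"] & r$y <= ext["ymax"]))
  cells <- cellFromXY(gridSpecOf(land$landcover), r$x, r$y)
  onWater <- rasterValues(land$landcover)[cbind(cells$row, cells$col)] ==
    landCoverCodes()[["WATER"]]
  expect_false(any(onWater))
  ## no cross-registry near-duplicates when duplication is off
  expect_equal(countCrossSourcePairs(fac, radius = 100), 0L)
})

test_that("registry duplication creates close cross-source pairs", {
  g <- gridSpec(80, 80, cellSize = 100)
  sc <- syntheticScenario(seed = 13, duplicateFraction = 0.5)
  fac <- generateFacilities(sc, generateLandscape(sc, g)$landcover)
  nMfl <- sum(facilityRecords(fac)$source == "MFL")
  expect_gte(countCrossSourcePairs(fac, radius = 200), round(0.5 * nMfl) * 1)
})
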