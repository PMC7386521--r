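test_that("travel time matches closed forms on a uniform forest grid", {
  land <- uniformLandCover(5, 5, "FOREST")  # 2 km/h everywhere
  fr <- buildFriction(land, NULL, defaultSpeedTable())
  tt <- rasterValues(costDistance(fr, data.frame(row = 3, col = 3)))
  expect_equal(tt[3, 3], 0)
  expect_equal(tt[3, 4], 3.0, tolerance = 1e-12)         # 100 m at 2 km/h
  expect_equal(tt[2, 2], 0.1 * sqrt(2) / 2 * 60, tolerance = 1e-12)
  ## exact closed form along full axis and diagonal lines
  expect_equal(tt[3, ], abs(1:5 - 3) * 3.0, tolerance = 1e-12)
  expect_equal(diag(tt), abs(1:5 - 3) * 0.1 * sqrt(2) / 2 * 60,
               tolerance = 1e-12)
})

test_that("multi-source travel time is the pointwise minimum of sources", {
  inst <- local({set.seed(501); randomFrictionInstance(15, 15, 2)})
  both <- rasterValues(costDistance(inst$friction, inst$sources))
  one <- rasterValues(costDistance(inst$friction, inst$sources[1, ]))
  two <- rasterValues(costDistance(inst$friction, inst$sources[2, ]))
  expect_equal(both, pmin(one, two))
})

test_that("production Dijkstra agrees with the brute-force oracle", {
  set.seed(77)
  for (k in 1:25) {
    nr <- sample(5:20, 1); nc <- sample(5:20, 1)
    inst <- randomFrictionInstance(nr, nc, sample(1:3, 1))
    got <- rasterValues(costDistance(inst$friction, inst$sources))
    want <- oracleCostDistance(inst$speed, inst$barrier, inst$sources,
                               inst$cellSize)
    expect_lt(relErr(got, want), 1e-9)
  }
})

test_that("adjacent travel times obey the local edge-time bound", {
  inst <- local({set.seed(88); randomFrictionInstance(20, 20, 2)})
  tt <- rasterValues(costDistance(inst$friction, inst$sources))
  pace <- 1 / inst$speed
  for (sh in list(c(0, 1), c(1, 0), c(1, 1))) {
    d <- 0.1 * if (all(sh == 1)) sqrt(2) else 1
    a <- tt[1:(20 - sh[1]), 1:(20 - sh[2])]
    b <- tt[(1 + sh[1]):20, (1 + sh[2]):20]
    w <- d * 0.5 * (pace[1:(20 - sh[1]), 1:(20 - sh[2])] +
                    pace[(1 + sh[1]):20, (1 + sh[2]):20]) * 60
    ok <- is.finite(a) & is.finite(b)
    expect_true(all(abs(a - b)[ok] <= w[ok] + 1e-9))
  }
})

test_that("barriers are never traversed and isolate unreachable pockets", {
  ## a wall of barrier splits the grid; the far side is unreachable
  speed <- matrix(10, 7, 7)
  speed[, 4] <- NA
  fr <- frictionFromSpeed(speed)
  tt <- rasterValues(costDistance(fr, data.frame(row = 4, col = 1)))
  expect_true(all(is.finite(tt[, 1:3])))
  expect_true(all(is.infinite(tt[, 4:7])))
})

test_that("facilities snap to cells, off barriers, or are dropped", {
  speed <- matrix(5, 9, 9)
  speed[5, 5] <- NA          # lone water cell
  speed[1:3, 7:9] <- NA      # big water block in a corner
  fr <- frictionFromSpeed(speed)
  g <- gridSpecOf(fr)
  ## facility at the exact centre of traversable cell (2,2)
  ctr <- xyFromCell(g, 2, 2)
  fac <- facilitySet("a", ctr$x, ctr$y, "OSM", "clinic")
  expect_equal(snapFacilities(fac, fr), data.frame(row = 2L, col = 2L),
               ignore_attr = TRUE)
  ## facility on the lone barrier cell snaps to an adjacent traversable cell
  wet <- xyFromCell(g, 5, 5)
  fac2 <- facilitySet("b", wet$x, wet$y, "OSM", "clinic")
  snapped <- snapFacilities(fac2, fr)
  expect_true(max(abs(c(snapped$row, snapped$col) - 5)) == 1)
  ## deep inside the water block, beyond a radius-1 search: dropped -> error
  deep <- xyFromCell(g, 1, 9)
  fac3 <- facilitySet("c", deep$x, deep$y, "OSM", "clinic")
  expect_warning(expect_error(snapFacilities(fac3, fr, maxRadius = 1),
                              "no facility"), "dropped")
  ## empty set is an error
  empty <- facilitySet(character(), numeric(), numeric(), character(),
                       character(), logical())
  expect_error(snapFacilities(empty, fr), "empty")
})

test_that("adding a facility never increases any cell's travel time", {
  set.seed(99)
  for (k in 1:5) {
    inst <- randomFrictionInstance(15, 15, 3)
    tt3 <- rasterValues(costDistance(inst$friction, inst$sources))
    tt2 <- rasterValues(costDistance(inst$friction, inst$sources[1:2, ]))
    expect_true(all(tt3 <= tt2 + 1e-12))
  }
})

test_that("region borders never constrain the path graph", {
  ## facility in the east 'region'; the west is populated: travel times in
  ## the west are finite because crossing the border costs nothing extra
  land <- uniformLandCover(10, 10, "BARREN")
  fr <- buildFriction(land, NULL, defaultSpeedTable())
  east <- xyFromCell(gridSpecOf(fr), 5, 10)
  fac <- facilitySet("h", east$x, east$y, "MFL", "hospital")
  tt <- costDistance(fr, snapFacilities(fac, fr))
  expect_true(all(is.finite(rasterValues(tt))))
})

test_that("aggregation to the population grid follows the finite-mean rule", {
  g <- gridSpec(20, 20, cellSize = 100)
  v <- matrix(5, 20, 20)
  v[1:10, 11:20] <- c(rep(2, 50), rep(Inf, 50))   # half finite, half not
  v[11:20, 1:10] <- Inf                           # fully unreachable block
  v[11:20, 11:20] <- NA                           # nodata block
  tt <- new("TravelTimeRaster", grid = g, values = v)
  agg <- rasterValues(aggregateTravelTime(tt, coarsenGrid(g, 10)))
  expect_equal(agg[1, 1], 5)
  expect_equal(agg[1, 2], 2)
  expect_true(is.infinite(agg[2, 1]))
  expect_true(is.na(agg[2, 2]))
  ## min / median variants
  v2 <- matrix(rep(1:4, each = 100), 20, 20)
  tt2 <- new("TravelTimeRaster", grid = g, values = v2)
  expect_equal(rasterValues(aggregateTravelTime(tt2, coarsenGrid(g, 10),
                                                "min"))[1, 1], 1)
})

test_that("travel-time rasters round-trip through ASCII grids", {
  g <- gridSpec(6, 6, cellSize = 1000)
  v <- matrix(stats::runif(36) * 100, 6, 6)
  v[1, 1] <- Inf; v[2, 2] <- NA
  tt <- new("TravelTimeRaster", grid = g, values = v)
  f <- tempfile(fileext = ".asc")
  writeAsciiGrid(tt, f)
  back <- readAsciiGrid(f, "TravelTimeRaster")
  expect_true(sameGrid(gridSpecOf(back), g))
  expect_equal(rasterValues(back), v, tolerance = 1e-9)
  expect_true(is.infinite(rasterValues(back)[1, 1]))
  expect_true(is.na(rasterValues(back)[2, 2]))
})
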