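test_that("Wilson interval matches its closed forms at the extremes", {
  z <- 1.959964
  ci0 <- wilsonInterval(0, 100, z)
  expect_equal(ci0[1, "low"], 0, ignore_attr = TRUE)
  expect_equal(ci0[1, "high"], z^2 / (100 + z^2), tolerance = 1e-12,
               ignore_attr = TRUE)
  ci1 <- wilsonInterval(1, 10, z)
  expect_equal(ci1[1, "low"], 10 / (10 + z^2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ci1[1, "high"], 1, ignore_attr = TRUE)
  ## symmetric about 0.5
  ci5 <- wilsonInterval(0.5, 37, z)
  expect_equal(ci5[1, "high"] - 0.5, 0.5 - ci5[1, "low"], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(wilsonInterval(0.5, 0), "n must be")
})

test_that("Wilson interval agrees with direct evaluation on a grid", {
  z <- 1.959964
  for (p in c(0, 0.01, 0.096, 0.25, 0.5, 0.909, 1)) {
    for (n in c(1, 5, 44, 1000, 1e6)) {
      got <- wilsonInterval(p, n, z)
      centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
      expect_equal(got[1, "low"], max(0, centre - half), tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_equal(got[1, "high"], min(1, centre + half), tolerance = 1e-12,
                   ignore_attr = TRUE)
      ## always contains the point estimate
      expect_true(got[1, "low"] <= p && p <= got[1, "high"])
    }
  }
  ## converges onto the point estimate as n grows
  big <- wilsonInterval(0.3, 1e8)
  expect_lt(big[1, "high"] - big[1, "low"], 1e-3)
})

test_that("proportion above a cutoff weights population, Inf counts above", {
  tt <- ttRaster(matrix(c(30, 400, 100), 1, 3))
  pop <- popRaster(matrix(c(10, 20, 70), 1, 3))
  est <- proportionAbove(tt, pop, 360, n = 3)
  expect_equal(est@pHat, 0.20)
  ## all below the cutoff
  expect_equal(proportionAbove(tt, pop, 500, n = 3)@pHat, 0)
  ## unreachable population exceeds every cutoff
  tt2 <- ttRaster(matrix(c(10, Inf, 10, 10, 10), 1, 5))
  pop2 <- popRaster(matrix(c(20, 5, 10, 10, 5), 1, 5))
  expect_equal(proportionAbove(tt2, pop2, 720, n = 5)@pHat, 0.10)
  ## non-increasing in the cutoff
  cuts <- c(30, 60, 120, 360, 720)
  ps <- vapply(cuts, function(ct) proportionAbove(tt2, pop2, ct, n = 5)@pHat,
               numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  ## zero population is an error
  expect_error(proportionAbove(tt, popRaster(matrix(0, 1, 3)), 60, n = 3),
               "zero")
})

test_that("weighted quantiles follow the midpoint cumulative-weight rule", {
  ## uniform weights on 1..100: top fifth is 81..100, median 90.5
  tt <- ttRaster(matrix(1:100, 10, 10))
  pop <- popRaster(matrix(1, 10, 10))
  q <- weightedQuantileStats(tt, pop, c(0.8, 1))
  expect_equal(q$median, 90.5)
  expect_equal(q$iqrLow, 85.5)
  expect_equal(q$iqrHigh, 95.5)
  ## brute-force check of the quantile primitive on an enumerated list
  x <- c(2, 5, 5, 9); w <- c(1, 1, 2, 4)
  p <- (cumsum(w) - w / 2) / sum(w)  # 0.0625 0.25 0.4375 0.75
  expect_equal(weightedQuantile(x, w, 0.25), 5)
  expect_equal(weightedQuantile(x, w, 0.5),
               5 + (9 - 5) * (0.5 - p[3]) / (p[4] - p[3]))
  expect_equal(weightedQuantile(x, w, 0.01), 2)   # clamped at the extremes
  expect_equal(weightedQuantile(x, w, 0.99), 9)
  ## degenerate distribution: median = t, IQR = (t, t)
  cst <- weightedQuantileStats(ttRaster(matrix(42, 4, 4)),
                               popRaster(matrix(2, 4, 4)))
  expect_equal(unlist(cst), c(median = 42, iqrLow = 42, iqrHigh = 42))
  ## scale invariance in the weights
  pop2 <- popRaster(matrix(2, 10, 10))
  expect_equal(weightedQuantileStats(tt, pop2, c(0.8, 1)), q)
  ## unreachable mass at the top makes the band statistics unreachable
  v <- matrix(10, 10, 10); v[, 9:10] <- Inf
  qInf <- weightedQuantileStats(ttRaster(v), pop, c(0.8, 1))
  expect_true(is.infinite(qInf$median))
  exclInf <- weightedQuantileStats(ttRaster(v), pop, c(0.8, 1),
                                   includeUnreachable = FALSE)
  expect_equal(exclInf$median, 10)
  expect_error(weightedQuantileStats(tt, pop, c(0.9, 0.2)), "quantileBand")
})

test_that("categorical map masks unpopulated cells and is closed-left", {
  tt <- ttRaster(matrix(c(90, 400, 120, 720, Inf, 50), 2, 3))
  pop <- popRaster(matrix(c(5, 1, 0.5, 2, 3, 0), 2, 3))
  m <- categorizeMap(tt, pop, hospitalCutoffs())
  v <- rasterValues(m)
  expect_equal(v[1, 1], 1L)            # 90 min < 2 h
  expect_equal(v[2, 1], 3L)            # 400 min in 6-12 h
  expect_true(is.na(v[1, 2]))          # pop 0.5 < 1: masked
  expect_equal(v[2, 2], 4L)            # exactly 720 goes up: closed-left
  expect_equal(v[1, 3], 4L)            # unreachable in the top category
  expect_true(is.na(v[2, 3]))          # unpopulated
  ## any-facility scheme: 400 min is beyond the 360 boundary
  m2 <- categorizeMap(ttRaster(matrix(400, 1, 1)),
                      popRaster(matrix(2, 1, 1)), anyFacilityCutoffs())
  expect_equal(rasterValues(m2)[1, 1], 4L)
  expect_equal(m2@labels[4], ">6h")
})

test_that("distribution table conserves population and bins unreachable", {
  tt <- ttRaster(matrix(c(0, 10, 29.9, 30, 65, Inf), 2, 3))
  pop <- popRaster(matrix(c(10, 20, 30, 40, 50, 60), 2, 3))
  tab <- distributionTable(tt, pop, binWidth = 30)
  expect_equal(sum(tab$population), 210)
  expect_equal(tab$population[1], 60)        # [0, 30): closed-left
  expect_equal(tab$population[2], 40)        # [30, 60) holds the 30 exactly
  expect_equal(tab$population[3], 50)        # [60, 90) holds the 65
  expect_equal(tab$population[tab$bin_low == Inf], 60)
  ## all population at time zero lands in the first bin
  tab0 <- distributionTable(ttRaster(matrix(0, 2, 2)),
                            popRaster(matrix(1, 2, 2)), binWidth = 30)
  expect_equal(tab0$population[1], 4)
  expect_equal(sum(tab0$population[-1]), 0)
  ## an empty region yields a zero-total histogram
  regions <- list(here = cbind(c(0, 3000, 3000, 0), c(0, 0, 2000, 2000)),
                  nowhere = cbind(c(1e6, 1e6 + 1, 1e6 + 1, 1e6),
                                  c(0, 0, 1, 1)))
  tabR <- distributionTable(tt, pop, 30, regions)
  expect_equal(sum(tabR$population[tabR$region == "nowhere"]), 0)
  expect_equal(sum(tabR$population[tabR$region == "here"]), 210)
})

test_that("access summary conserves shares and reports the right columns", {
  set.seed(31)
  tt <- ttRaster(matrix(c(stats::runif(98, 0, 900), Inf, Inf), 10, 10))
  pop <- popRaster(matrix(stats::rlnorm(100, 2, 1), 10, 10))
  s <- accessSummary(tt, pop, hospitalCutoffs(), cutoff = 360, wilsonN = 100)
  tb <- summaryTable(s)
  shares <- unlist(tb[1, grep("^share_", names(tb))])
  shareCats <- shares[setdiff(names(shares), "share_unreachable")]
  expect_equal(sum(shareCats), 1, tolerance = 1e-9)
  expect_true(tb$ci_low <= tb$p_above_cutoff &
                tb$p_above_cutoff <= tb$ci_high)
  expect_equal(tb$total_pop, sum(rasterValues(pop)))
  expect_true(tb$share_unreachable > 0)
})
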