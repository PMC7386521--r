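## Shared fixtures: tiny rasters built in code, plus an independent
## brute-force shortest-path oracle.

uniformLandCover <- function(nr, nc, class = "BARREN", cellSize = 100) {
  g <- gridSpec(nr, nc, cellSize = cellSize)
  new("LandCoverRaster", grid = g,
      values = matrix(landCoverCodes()[[class]], nr, nc))
}

## friction surface directly from a speed matrix (NA = barrier)
frictionFromSpeed <- function(speed, cellSize = 100) {
  g <- gridSpec(nrow(speed), ncol(speed), cellSize = cellSize)
  new("FrictionSurface", grid = g, values = speed,
      barrierMask = is.na(speed))
}

ttRaster <- function(minutes, cellSize = 1000) {
  g <- gridSpec(nrow(minutes), ncol(minutes), cellSize = cellSize)
  new("TravelTimeRaster", grid = g, values = minutes)
}

popRaster <- function(counts, cellSize = 1000) {
  g <- gridSpec(nrow(counts), ncol(counts), cellSize = cellSize)
  new("PopulationRaster", grid = g, values = counts)
}

## Independent oracle: brute-force Bellman-Ford relaxation over the full
## 8-neighbour edge set, iterated to an exact fixed point. Shares no code
## with the production Dijkstra.
oracleCostDistance <- function(speed, barrier, sources, cellSize) {
  nr <- nrow(speed); nc <- ncol(speed)
  pace <- 1 / speed
  pace[barrier] <- Inf
  D <- matrix(Inf, nr, nc)
  D[as.matrix(sources[, c("row", "col")])] <- 0
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    r1 <- max(1, 1 + dr):min(nr, nr + dr)
    c1 <- max(1, 1 + dc):min(nc, nc + dc)
    out[r1, c1] <- m[r1 - dr, c1 - dc]
    out
  }
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  repeat {
    Dn <- D
    for (k in 1:8) {
      dr <- offs[k, 1]; dc <- offs[k, 2]
      d <- cellSize / 1000 * if (dr != 0 && dc != 0) sqrt(2) else 1
      W <- d * 0.5 * (pace + shift(pace, dr, dc)) * 60
      Dn <- pmin(Dn, shift(D, dr, dc) + W)
    }
    Dn[barrier] <- Inf
    if (identical(Dn, D)) break
    D <- Dn
  }
  D
}

## random friction instance for oracle comparisons
randomFrictionInstance <- function(nr, nc, nSources, barrierProb = 0.15,
                                   cellSize = 100) {
  speed <- matrix(stats::runif(nr * nc, 1, 100), nr, nc)
  barrier <- matrix(stats::runif(nr * nc) < barrierProb, nr, nc)
  open <- which(!barrier)
  if (length(open) < nSources) barrier[] <- FALSE
  open <- which(!barrier)
  src <- arrayInd(sample(open, nSources), c(nr, nc))
  speed[barrier] <- NA_real_
  list(friction = frictionFromSpeed(speed, cellSize),
       sources = data.frame(row = src[, 1], col = src[, 2]),
       speed = speed, barrier = barrier, cellSize = cellSize)
}

relErr <- function(a, b) {
  fin <- is.finite(a) & is.finite(b)
  if (!identical(is.finite(a), is.finite(b)) ||
      !identical(is.na(a), is.na(b))) return(Inf)
  if (!any(fin)) return(0)
  max(abs(a[fin] - b[fin]) / pmax(1, abs(b[fin])))
}
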