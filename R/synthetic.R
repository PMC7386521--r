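#' @include AllClasses.R grid.R
NULL

#' ElevationRaster: terrain elevation in metres
#' @export
setClass("ElevationRaster", contains = "GridLayer")

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state:
## generators stay pure functions of (scenario, grid).
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(expr)
}

## Deterministic sub-stream offsets per generator, all derived from the one
## scenario seed.
.SUBSEED <- c(settlements = 11L, landcover = 29L, roads = 47L,
              population = 71L, facilities = 97L, elevation = 131L)

#' Settlement centres of a synthetic scenario
#'
#' Settlement locations are the shared skeleton of the synthetic world:
#' population kernels, facilities and the road network all hang off them.
#' Deterministic given (scenario, grid).
#'
#' @param scenario a [SyntheticScenario-class].
#' @param grid the model [GridSpec-class].
#' @return Matrix `nSettlements` x 2 of planar coordinates (metres).
#' @export
settlementCenters <- function(scenario, grid) {
  ext <- gridExtent(grid)
  .withSeed(scenario@seed + .SUBSEED[["settlements"]], {
    pad <- 0.08
    dx <- ext["xmax"] - ext["xmin"]; dy <- ext["ymax"] - ext["ymin"]
    x <- stats::runif(scenario@nSettlements, ext["xmin"] + pad * dx,
                      ext["xmax"] - pad * dx)
    y <- stats::runif(scenario@nSettlements, ext["ymin"] + pad * dy,
                      ext["ymax"] - pad * dy)
    cbind(x = x, y = y)
  })
}

## Grow contiguous blobs of `target` cells over the logical matrix `free`
## (TRUE = available), 4-connected random dilation. Returns logical mask.
.growBlobs <- function(nr, nc, free, target, nBlobs) {
  mask <- matrix(FALSE, nr, nc)
  if (target <= 0) return(mask)
  avail <- which(free)
  if (!length(avail)) return(mask)
  seeds <- sample(avail, min(nBlobs, length(avail)))
  mask[seeds] <- TRUE
  while (sum(mask) < target) {
    idx <- which(mask & free)
    r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
    nb <- rbind(cbind(r - 1L, c), cbind(r + 1L, c),
                cbind(r, c - 1L), cbind(r, c + 1L))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= nc, ,
             drop = FALSE]
    cand <- unique((nb[, 2] - 1L) * nr + nb[, 1])
    cand <- cand[free[cand] & !mask[cand]]
    if (!length(cand)) break  # blob boxed in; accept the shortfall
    take <- cand[stats::runif(length(cand)) < 0.7]
    if (!length(take)) take <- cand[1L]
    need <- target - sum(mask)
    if (length(take) > need) take <- sample(take, need)
    mask[take] <- TRUE
  }
  mask
}

#' Generate a synthetic landscape
#'
#' Builds a categorical land-cover raster (barren background, contiguous
#' water and forest blobs, built-up cores at settlements), a road network
#' connecting the settlement centres by the edges of their Euclidean minimum
#' spanning tree, and a smooth synthetic elevation surface. All outputs are
#' deterministic given the scenario seed.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param grid the model [GridSpec-class] (100 m cells by convention).
#' @return list with elements `landcover` ([LandCoverRaster-class]),
#'   `roads` ([RoadNetwork-class]), `elevation` ([ElevationRaster-class]).
#' @examples
#' sc <- syntheticScenario(seed = 7, nSettlements = 5)
#' g <- gridSpec(80, 80, cellSize = 100)
#' land <- generateLandscape(sc, g)
#' table(rasterValues(land$landcover))
#' @export
generateLandscape <- function(scenario, grid) {
  validObject(scenario); validObject(grid)
  nr <- grid@nRows; nc <- grid@nCols; ncell <- nr * nc
  codes <- .LAND_COVER_CODES
  centers <- settlementCenters(scenario, grid)
  cc <- cellFromXY(grid, centers[, 1], centers[, 2])

  lc <- matrix(codes[["BARREN"]], nr, nc)

  ## keep settlement cores dry: water seeds avoid a 500 m buffer
  protect <- matrix(FALSE, nr, nc)
  buf <- max(2L, as.integer(round(500 / grid@cellSize)))
  for (k in seq_len(nrow(cc))) {
    r0 <- max(1L, cc$row[k] - buf); r1 <- min(nr, cc$row[k] + buf)
    c0 <- max(1L, cc$col[k] - buf); c1 <- min(nc, cc$col[k] + buf)
    protect[r0:r1, c0:c1] <- TRUE
  }

  water <- .withSeed(scenario@seed + .SUBSEED[["landcover"]], {
    nWater <- round(scenario@waterFraction * ncell)
    w <- .growBlobs(nr, nc, !protect, nWater,
                    nBlobs = max(1L, round(nWater / 4000)))
    forestTarget <- round(scenario@forestFraction * ncell)
    f <- .growBlobs(nr, nc, !w, forestTarget,
                    nBlobs = max(1L, round(forestTarget / 6000)))
    list(w = w, f = f)
  })
  lc[water$f] <- codes[["FOREST"]]
  lc[water$w] <- codes[["WATER"]]

  ## built-up cores (~300 m radius) at settlements, never over water
  core <- max(1L, as.integer(round(300 / grid@cellSize)))
  for (k in seq_len(nrow(cc))) {
    r0 <- max(1L, cc$row[k] - core); r1 <- min(nr, cc$row[k] + core)
    c0 <- max(1L, cc$col[k] - core); c1 <- min(nc, cc$col[k] + core)
    blk <- lc[r0:r1, c0:c1]
    blk[blk != codes[["WATER"]]] <- codes[["BUILT_UP"]]
    lc[r0:r1, c0:c1] <- blk
  }

  roads <- .withSeed(scenario@seed + .SUBSEED[["roads"]],
                     .mstRoads(centers))

  elev <- .withSeed(scenario@seed + .SUBSEED[["elevation"]], {
    nb <- 6L
    ext <- gridExtent(grid)
    bx <- stats::runif(nb, ext["xmin"], ext["xmax"])
    by <- stats::runif(nb, ext["ymin"], ext["ymax"])
    amp <- stats::runif(nb, 50, 400)
    sig <- stats::runif(nb, 0.1, 0.3) * (ext["xmax"] - ext["xmin"])
    xc <- grid@originX + (seq_len(nc) - 0.5) * grid@cellSize
    yc <- grid@originY - (seq_len(nr) - 0.5) * grid@cellSize
    e <- matrix(0, nr, nc)
    for (b in seq_len(nb))
      e <- e + amp[b] * outer(exp(-(yc - by[b])^2 / (2 * sig[b]^2)),
                              exp(-(xc - bx[b])^2 / (2 * sig[b]^2)))
    e
  })

  list(landcover = new("LandCoverRaster", grid = grid, values = lc),
       roads = roads,
       elevation = new("ElevationRaster", grid = grid, values = elev))
}

## Euclidean minimum spanning tree over settlement centres (Prim), each edge
## a straight polyline; longest edges become primary roads, shortest tertiary.
.mstRoads <- function(centers) {
  n <- nrow(centers)
  if (n < 2L) return(roadNetwork(list()))
  d <- as.matrix(stats::dist(centers))
  inTree <- c(TRUE, rep(FALSE, n - 1L))
  edges <- matrix(0L, n - 1L, 2L)
  for (k in seq_len(n - 1L)) {
    dd <- d[inTree, !inTree, drop = FALSE]
    pick <- which(dd == min(dd), arr.ind = TRUE)[1L, ]
    from <- which(inTree)[pick[1L]]; to <- which(!inTree)[pick[2L]]
    edges[k, ] <- c(from, to)
    inTree[to] <- TRUE
  }
  len <- sqrt(rowSums((centers[edges[, 1L], , drop = FALSE] -
                       centers[edges[, 2L], , drop = FALSE])^2))
  rk <- rank(-len, ties.method = "first")
  cls <- .ROAD_CLASSES[pmin(3L, ceiling(rk / max(1, length(len) / 3)))]
  segs <- lapply(seq_len(nrow(edges)), function(k)
    list(coords = centers[edges[k, ], , drop = FALSE], class = cls[k]))
  roadNetwork(segs)
}

#' Generate a synthetic population raster
#'
#' Adults aged 60+ are distributed over the coarse grid by isotropic Gaussian
#' kernels centred on the settlements (scale `settlementSpread`), modulated
#' by mild seeded lognormal noise, zeroed on water-dominated cells, and
#' normalised so the raster total equals `scenario@totalPopulation` exactly
#' (up to floating point).
#'
#' @param scenario a [SyntheticScenario-class].
#' @param landcover the model-resolution [LandCoverRaster-class].
#' @param grid1km the coarse population [GridSpec-class]; must cover the same
#'   extent as the land-cover grid (nested blocks).
#' @return A [PopulationRaster-class] on `grid1km`.
#' @export
generatePopulation <- function(scenario, landcover, grid1km) {
  validObject(scenario)
  f <- .nestingFactor(landcover@grid, grid1km)
  nr <- grid1km@nRows; nc <- grid1km@nCols

  ## fraction of habitable (non-water) fine cells per coarse cell
  isWater <- landcover@values == .LAND_COVER_CODES[["WATER"]]
  habitable <- 1 - .blockReduce(isWater + 0, f, mean)

  centers <- settlementCenters(scenario, landcover@grid)
  xc <- grid1km@originX + (seq_len(nc) - 0.5) * grid1km@cellSize
  yc <- grid1km@originY - (seq_len(nr) - 0.5) * grid1km@cellSize
  s2 <- 2 * scenario@settlementSpread^2
  w <- matrix(0, nr, nc)
  for (k in seq_len(nrow(centers)))
    w <- w + outer(exp(-(yc - centers[k, 2])^2 / s2),
                   exp(-(xc - centers[k, 1])^2 / s2))
  w <- w * habitable
  w <- .withSeed(scenario@seed + .SUBSEED[["population"]],
                 w * matrix(stats::rlnorm(nr * nc, 0, 0.3), nr, nc))
  tot <- sum(w)
  if (tot <= 0) {
    if (scenario@totalPopulation > 0)
      stop("no habitable cell available to place population on", call. = FALSE)
    counts <- matrix(0, nr, nc)
  } else {
    counts <- w / tot * scenario@totalPopulation
  }
  new("PopulationRaster", grid = grid1km, values = counts)
}

## reduce a matrix over f x f blocks with `fun`
.blockReduce <- function(m, f, fun) {
  nr <- nrow(m) %/% f; nc <- ncol(m) %/% f
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[i, j] <- fun(m[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
  out
}

#' Generate synthetic facility registries
#'
#' Places the requested number of facilities per (source, type) near
#' settlement centres on non-water cells, then duplicates a fraction of MFL
#' records into the OSM registry with a small coordinate jitter, emulating
#' two partially overlapping registries that are pooled without
#' deduplication downstream.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param landcover the model-resolution [LandCoverRaster-class].
#' @return A [FacilitySet-class].
#' @export
generateFacilities <- function(scenario, landcover) {
  validObject(scenario)
  grid <- landcover@grid
  isWater <- landcover@values == .LAND_COVER_CODES[["WATER"]]
  if (all(isWater))
    stop("cannot place facilities: landscape has no non-water cell",
         call. = FALSE)
  centers <- settlementCenters(scenario, grid)
  ext <- gridExtent(grid)
  fc <- scenario@facilityCounts

  .withSeed(scenario@seed + .SUBSEED[["facilities"]], {
    rec <- list()
    for (r in seq_len(nrow(fc))) {
      n <- fc$n[r]
      if (n == 0L) next
      xy <- matrix(NA_real_, n, 2)
      for (k in seq_len(n)) {
        for (try in 1:200) {
          s <- sample(nrow(centers), 1L)
          p <- centers[s, ] + stats::rnorm(2, 0, scenario@settlementSpread / 2)
          p[1] <- min(max(p[1], ext["xmin"] + 1), ext["xmax"] - 1)
          p[2] <- min(max(p[2], ext["ymin"] + 1), ext["ymax"] - 1)
          cell <- cellFromXY(grid, p[1], p[2])
          if (!isWater[cell$row, cell$col]) { xy[k, ] <- p; break }
        }
        if (is.na(xy[k, 1]))
          stop("could not place a facility on a non-water cell",
               call. = FALSE)
      }
      rec[[length(rec) + 1L]] <- data.frame(
        id = sprintf("%s_%s_%03d", fc$source[r], fc$type[r], seq_len(n)),
        x = xy[, 1], y = xy[, 2], source = fc$source[r],
        raw_type = fc$type[r],
        is_hospital = classifyFacility(fc$type[r]),
        stringsAsFactors = FALSE)
    }
    df <- if (length(rec)) do.call(rbind, rec) else
      data.frame(id = character(), x = numeric(), y = numeric(),
                 source = character(), raw_type = character(),
                 is_hospital = logical(), stringsAsFactors = FALSE)

    ## cross-registry duplicates: MFL records re-listed in OSM with jitter
    mfl <- which(df$source == "MFL")
    nDup <- round(scenario@duplicateFraction * length(mfl))
    if (nDup > 0) {
      pick <- sample(mfl, nDup)
      dup <- df[pick, , drop = FALSE]
      dup$x <- dup$x + stats::rnorm(nDup, 0, 30)
      dup$y <- dup$y + stats::rnorm(nDup, 0, 30)
      dup$x <- pmin(pmax(dup$x, ext["xmin"] + 1), ext["xmax"] - 1)
      dup$y <- pmin(pmax(dup$y, ext["ymin"] + 1), ext["ymax"] - 1)
      cells <- cellFromXY(grid, dup$x, dup$y)
      wet <- isWater[cbind(cells$row, cells$col)]
      dup$x[wet] <- df$x[pick][wet]  # jitter pushed it into water: keep original
      dup$y[wet] <- df$y[pick][wet]
      dup$source <- "OSM"
      dup$id <- sprintf("OSM_dup_%03d", seq_len(nDup))
      df <- rbind(df, dup)
    }
    rownames(df) <- NULL
    new("FacilitySet", records = df)
  })
}
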