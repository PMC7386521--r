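#' @include AllClasses.R grid.R friction.R
#' @useDynLib geoaccess, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Snap facilities to traversable source cells
#'
#' Maps each facility to its containing cell. A facility that lands on a
#' barrier cell (e.g. a geocode in open water) is snapped to the nearest
#' traversable cell within `maxRadius` cells (Chebyshev rings, nearest by
#' Euclidean cell-centre distance, ties broken by row then column); if none
#' exists within the radius the facility is dropped with a warning.
#'
#' @param facilities a [FacilitySet-class]; must be non-empty.
#' @param friction a [FrictionSurface-class].
#' @param maxRadius snap search radius in cells.
#' @return data.frame with columns `row`, `col` (one per retained facility).
#' @export
snapFacilities <- function(facilities, friction, maxRadius = 10L) {
  r <- facilities@records
  if (!nrow(r)) stop("facility set is empty: no source cells", call. = FALSE)
  grid <- friction@grid
  cells <- cellFromXY(grid, r$x, r$y)
  if (anyNA(cells$row))
    stop("facilities outside the grid extent: ",
         paste(r$id[is.na(cells$row)], collapse = ", "), call. = FALSE)
  bar <- friction@barrierMask
  nr <- grid@nRows; nc <- grid@nCols
  out <- vector("list", nrow(r))
  dropped <- character()
  for (k in seq_len(nrow(r))) {
    i <- cells$row[k]; j <- cells$col[k]
    if (!bar[i, j]) { out[[k]] <- c(i, j); next }
    best <- NULL; bestD <- Inf
    for (rad in seq_len(maxRadius)) {
      ii <- max(1L, i - rad):min(nr, i + rad)
      jj <- max(1L, j - rad):min(nc, j + rad)
      ring <- expand.grid(row = ii, col = jj)
      ring <- ring[pmax(abs(ring$row - i), abs(ring$col - j)) == rad, ]
      ring <- ring[!bar[cbind(ring$row, ring$col)], , drop = FALSE]
      if (nrow(ring)) {
        d <- sqrt((ring$row - i)^2 + (ring$col - j)^2)
        ord <- order(d, ring$row, ring$col)
        if (d[ord[1]] < bestD) { best <- ring[ord[1], ]; bestD <- d[ord[1]] }
        ## a nearer cell can still appear one ring further out (Euclidean
        ## vs Chebyshev), so look one extra ring before accepting
        if (rad > bestD) break
      }
    }
    if (is.null(best)) dropped <- c(dropped, r$id[k])
    else out[[k]] <- c(best$row, best$col)
  }
  if (length(dropped))
    warning(sprintf("dropped %d facility(ies) with no traversable cell %s: %s",
                    length(dropped), "within the snap radius",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    stop("no facility could be snapped to a traversable cell", call. = FALSE)
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("row", "col")
  df
}

#' Least-cost travel time to the nearest source cell
#'
#' Exact multi-source Dijkstra over the 8-connected raster graph. The edge
#' time between adjacent cells a and b is `d(a,b) * (1/v_a + 1/v_b) / 2`,
#' with `d` the cell size for axis moves and `cellSize * sqrt(2)` for
#' diagonal moves: travel time accrues half in each cell at that cell's
#' speed. Barrier cells are excluded from the graph entirely. The result is
#' in minutes; cells with no barrier-free path to any source (including
#' barrier cells themselves) carry `Inf`.
#'
#' @param friction a [FrictionSurface-class].
#' @param sources data.frame with columns `row`, `col` (from
#'   [snapFacilities()]), at least one on a traversable cell.
#' @return A [TravelTimeRaster-class] on the friction grid.
#' @examples
#' g <- gridSpec(3, 3, cellSize = 100)
#' lc <- new("LandCoverRaster", grid = g,
#'           values = matrix(landCoverCodes()[["FOREST"]], 3, 3))
#' fr <- buildFriction(lc, NULL, defaultSpeedTable())
#' tt <- costDistance(fr, data.frame(row = 2, col = 2))
#' rasterValues(tt)[2, 3]  # 3 minutes: 100 m at 2 km/h
#' @export
costDistance <- function(friction, sources) {
  validObject(friction)
  if (!nrow(sources)) stop("need at least one source cell", call. = FALSE)
  src <- as.matrix(sources[, c("row", "col")])
  storage.mode(src) <- "integer"
  nodata <- is.na(friction@values) & !friction@barrierMask
  minutes <- dijkstra_grid(friction@values, friction@barrierMask | nodata,
                           src, friction@grid@cellSize)
  minutes[nodata] <- NA_real_
  new("TravelTimeRaster", grid = friction@grid, values = minutes)
}

#' Travel time to the nearest facility of a target class
#'
#' Convenience wrapper: filters the facility set (`"hospital"` keeps hospital
#' records, `"any"` keeps everything), snaps to the friction surface and runs
#' [costDistance()].
#'
#' @param friction a [FrictionSurface-class].
#' @param facilities a [FacilitySet-class].
#' @param class `"hospital"` or `"any"`.
#' @param maxRadius snap radius in cells, see [snapFacilities()].
#' @return A [TravelTimeRaster-class].
#' @export
travelTimeTo <- function(friction, facilities, class = c("any", "hospital"),
                         maxRadius = 10L) {
  class <- match.arg(class)
  fac <- if (class == "hospital") hospitalsOnly(facilities) else facilities
  if (!nFacilities(fac))
    stop("no facility of class '", class, "' in the set", call. = FALSE)
  costDistance(friction, snapFacilities(fac, friction, maxRadius))
}

#' Aggregate a travel-time raster to a coarser nested grid
#'
#' Each coarse cell summarises the finite travel times of its block of fine
#' cells with `stat` (mean by default). A block with no finite value but at
#' least one unreachable fine cell is unreachable (`Inf`); a block that is
#' entirely nodata stays `NA`.
#'
#' @param tt a [TravelTimeRaster-class] on the fine (model) grid.
#' @param gridCoarse the coarse [GridSpec-class]; must nest exactly.
#' @param stat `"mean"`, `"min"` or `"median"` over finite block values.
#' @return A [TravelTimeRaster-class] on `gridCoarse`.
#' @export
aggregateTravelTime <- function(tt, gridCoarse,
                                stat = c("mean", "min", "median")) {
  stat <- match.arg(stat)
  f <- .nestingFactor(tt@grid, gridCoarse)
  fun <- switch(stat, mean = mean, min = min, median = stats::median)
  agg <- .blockReduce(tt@values, f, function(block) {
    fin <- block[is.finite(block)]
    if (length(fin)) return(fun(fin))
    if (all(is.na(block))) return(NA_real_)
    Inf
  })
  new("TravelTimeRaster", grid = gridCoarse, values = agg)
}
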