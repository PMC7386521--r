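#' @include AllClasses.R grid.R
NULL

#' RoadClassRaster: rasterized road classes
#'
#' Integer raster: 0 for no road, otherwise the index of the cell's fastest
#' road class in [roadClasses()] (1 = PRIMARY).
#'
#' @export
setClass("RoadClassRaster", contains = "GridLayer")

#' Rasterize a road network onto a grid
#'
#' Every cell whose interior is crossed by a segment's polyline receives that
#' segment's class; where several classes cross one cell the fastest wins
#' (PRIMARY over SECONDARY over TERTIARY). Polylines are traced by dense
#' sampling at a quarter of the cell size, which marks every crossed cell for
#' the straight segments used here. Segments lying entirely outside the grid
#' are skipped with a warning.
#'
#' @param roads a [RoadNetwork-class].
#' @param grid the target [GridSpec-class].
#' @return A [RoadClassRaster-class].
#' @export
rasterizeRoads <- function(roads, grid) {
  validObject(roads)
  nr <- grid@nRows; nc <- grid@nCols
  ## store class rank; smaller = faster; 4L = no road (sentinel for pmin)
  rank <- matrix(4L, nr, nc)
  step <- grid@cellSize / 4
  nOutside <- 0L
  for (seg in roads@segments) {
    cl <- match(seg$class, .ROAD_CLASSES)
    touched <- FALSE
    for (v in seq_len(nrow(seg$coords) - 1L)) {
      p0 <- seg$coords[v, ]; p1 <- seg$coords[v + 1L, ]
      len <- sqrt(sum((p1 - p0)^2))
      ts <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
      cells <- cellFromXY(grid, p0[1] + ts * (p1[1] - p0[1]),
                          p0[2] + ts * (p1[2] - p0[2]))
      ok <- !is.na(cells$row)
      if (any(ok)) {
        touched <- TRUE
        idx <- cbind(cells$row[ok], cells$col[ok])
        rank[idx] <- pmin(rank[idx], cl)
      }
    }
    if (!touched) nOutside <- nOutside + 1L
  }
  if (nOutside > 0L)
    warning(sprintf("%d road segment(s) lie entirely outside the grid %s",
                    nOutside, "and were ignored"), call. = FALSE)
  rank[rank == 4L] <- 0L
  new("RoadClassRaster", grid = grid, values = rank)
}

#' Build the friction (impedance) surface
#'
#' Combines land cover, rasterized roads and the speed table into a per-cell
#' traversal speed raster. A cell's speed is its road-class speed when a road
#' is present, otherwise its land-cover speed. Open water is an absolute
#' barrier to travel — except where a road crosses it, which models bridges
#' and causeways (roads override land cover unconditionally).
#'
#' An optional slope correction multiplies walking speeds (cells without
#' roads) by a Tobler-style exponential decay in the local slope magnitude,
#' normalised to 1 on flat terrain. This is a documented extension, off by
#' default; the base model uses land cover and roads only.
#'
#' @param landcover a [LandCoverRaster-class].
#' @param roadRaster a [RoadClassRaster-class] on the same grid (or `NULL`
#'   for no roads).
#' @param speeds a [SpeedTable-class].
#' @param elevation optional [ElevationRaster-class] for the slope correction.
#' @param slopeAdjust logical; apply the Tobler-style walking-speed decay.
#' @return A [FrictionSurface-class] (km/h; barrier cells `NA`).
#' @examples
#' g <- gridSpec(3, 3, cellSize = 100)
#' lc <- new("LandCoverRaster", grid = g,
#'           values = matrix(landCoverCodes()[["BARREN"]], 3, 3))
#' fr <- buildFriction(lc, NULL, defaultSpeedTable())
#' rasterValues(fr)[1, 1]  # 5 km/h: 72 s to cross a 100 m cell
#' @export
buildFriction <- function(landcover, roadRaster, speeds = defaultSpeedTable(),
                          elevation = NULL, slopeAdjust = FALSE) {
  validObject(landcover); validObject(speeds)
  grid <- landcover@grid
  lc <- landcover@values
  codes <- .LAND_COVER_CODES
  known <- codes[names(codes) %in% c(names(speeds@speeds), speeds@barriers)]
  bad <- setdiff(unique(lc[!is.na(lc)]), codes)
  if (length(bad))
    stop("unknown land-cover code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  missingClass <- setdiff(names(codes)[codes %in% unique(lc[!is.na(lc)])],
                          c(names(speeds@speeds), speeds@barriers))
  if (length(missingClass))
    stop("speed table has no entry for land-cover class(es): ",
         paste(missingClass, collapse = ", "), call. = FALSE)

  speed <- matrix(NA_real_, grid@nRows, grid@nCols)
  for (nm in names(codes)) {
    sel <- !is.na(lc) & lc == codes[[nm]]
    if (nm %in% speeds@barriers) next
    speed[sel] <- speeds@speeds[[nm]]
  }

  if (slopeAdjust) {
    if (is.null(elevation))
      stop("slopeAdjust = TRUE requires an elevation raster", call. = FALSE)
    .stopIfGridMismatch(grid, elevation@grid, "land cover and elevation")
    fac <- .toblerFactor(elevation@values, grid@cellSize)
    walk <- !is.na(lc) & lc %in% codes[c("BARREN", "BUILT_UP", "FOREST")]
    speed[walk] <- speed[walk] * fac[walk]
  }

  if (!is.null(roadRaster)) {
    .stopIfGridMismatch(grid, roadRaster@grid, "land cover and road raster")
    rr <- roadRaster@values
    for (k in seq_along(.ROAD_CLASSES)) {
      cls <- .ROAD_CLASSES[k]
      if (!cls %in% names(speeds@speeds))
        stop("speed table has no entry for road class ", cls, call. = FALSE)
      speed[rr == k] <- speeds@speeds[[cls]]  # roads win, bridges over water
    }
  }

  barrier <- is.na(speed) & !is.na(lc)
  speed[is.na(lc)] <- NA_real_
  new("FrictionSurface", grid = grid, values = speed, barrierMask = barrier)
}

## Tobler-style multiplicative walking-speed factor, 1 on flat terrain:
## exp(-3.5 * |S + 0.05|) / exp(-3.5 * 0.05) with S the slope magnitude
## (isotropic; sign of travel direction unknown on a cost raster).
.toblerFactor <- function(elev, cellSize) {
  nr <- nrow(elev); nc <- ncol(elev)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  if (nc >= 2) {
    if (nc >= 3)
      gx[, 2:(nc - 1)] <- (elev[, 3:nc] - elev[, 1:(nc - 2)]) / (2 * cellSize)
    gx[, 1] <- (elev[, 2] - elev[, 1]) / cellSize
    gx[, nc] <- (elev[, nc] - elev[, nc - 1]) / cellSize
  }
  if (nr >= 2) {
    if (nr >= 3)
      gy[2:(nr - 1), ] <- (elev[3:nr, ] - elev[1:(nr - 2), ]) / (2 * cellSize)
    gy[1, ] <- (elev[2, ] - elev[1, ]) / cellSize
    gy[nr, ] <- (elev[nr, ] - elev[nr - 1, ]) / cellSize
  }
  s <- sqrt(gx^2 + gy^2)
  exp(-3.5 * abs(s + 0.05)) / exp(-3.5 * 0.05)
}
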