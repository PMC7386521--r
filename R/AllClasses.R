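#' @import methods
NULL

## Land-cover class codes used throughout the package. Codes are stable
## integers so rasters round-trip through plain-text grids losslessly.
.LAND_COVER_CODES <- c(WATER = 1L, FOREST = 2L, BARREN = 3L, BUILT_UP = 4L)
.ROAD_CLASSES <- c("PRIMARY", "SECONDARY", "TERTIARY")
.FACILITY_SOURCES <- c("OSM", "MFL")

#' Land-cover class codes
#'
#' Integer codes for the four land-cover classes the friction model
#' understands: open water (a travel barrier), forest, barren land and
#' built-up areas.
#'
#' @return Named integer vector `c(WATER=1, FOREST=2, BARREN=3, BUILT_UP=4)`.
#' @export
landCoverCodes <- function() .LAND_COVER_CODES

#' Road class labels
#'
#' @return Character vector of the recognised road classes, fastest first.
#' @export
roadClasses <- function() .ROAD_CLASSES

#' GridSpec: planar raster grid definition
#'
#' Describes a regular planar grid in metres: dimensions, cell size and the
#' coordinates of the grid's top-left corner. Row indices increase downwards
#' (decreasing y), column indices increase rightwards (increasing x). Two
#' raster layers are combinable only if their GridSpecs are identical.
#'
#' @slot nRows,nCols integer grid dimensions (at least 1 each).
#' @slot cellSize cell edge length in metres (positive).
#' @slot originX,originY planar coordinates (metres) of the top-left corner.
#' @slot nodata numeric sentinel used when the layer is written to disk.
#' @export
setClass("GridSpec",
  representation(nRows = "integer", nCols = "integer", cellSize = "numeric",
                 originX = "numeric", originY = "numeric", nodata = "numeric"),
  prototype(nRows = 1L, nCols = 1L, cellSize = 100, originX = 0, originY = 0,
            nodata = -9999))

setValidity("GridSpec", function(object) {
  msgs <- character()
  if (length(object@nRows) != 1L || is.na(object@nRows) || object@nRows < 1L)
    msgs <- c(msgs, "nRows must be a single integer >= 1")
  if (length(object@nCols) != 1L || is.na(object@nCols) || object@nCols < 1L)
    msgs <- c(msgs, "nCols must be a single integer >= 1")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msgs <- c(msgs, "cellSize must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GridSpec
#'
#' @param nRows,nCols grid dimensions.
#' @param cellSize cell edge length in metres.
#' @param originX,originY planar coordinates of the top-left corner (metres).
#' @param nodata sentinel value for missing cells in on-disk representations.
#' @return A [GridSpec-class] object.
#' @examples
#' gridSpec(100, 100, cellSize = 100)
#' @export
gridSpec <- function(nRows, nCols, cellSize = 100, originX = 0,
                     originY = nRows * cellSize, nodata = -9999) {
  new("GridSpec", nRows = as.integer(nRows), nCols = as.integer(nCols),
      cellSize = as.numeric(cellSize), originX = as.numeric(originX),
      originY = as.numeric(originY), nodata = as.numeric(nodata))
}

#' GridLayer: a raster layer bound to a GridSpec
#'
#' Virtual parent of all matrix-backed raster layers. The `values` matrix has
#' `nRows(grid)` rows and `nCols(grid)` columns; `NA` marks nodata cells.
#'
#' @slot grid the [GridSpec-class] shared by combinable layers.
#' @slot values numeric or integer matrix of cell values.
#' @export
setClass("GridLayer", representation("VIRTUAL", grid = "GridSpec",
                                     values = "matrix"))

setValidity("GridLayer", function(object) {
  d <- dim(object@values)
  if (d[1] != object@grid@nRows || d[2] != object@grid@nCols)
    return(sprintf("values matrix is %dx%d but grid is %dx%d",
                   d[1], d[2], object@grid@nRows, object@grid@nCols))
  TRUE
})

#' LandCoverRaster: categorical land-cover layer
#'
#' Integer raster whose non-`NA` cells carry one of the codes returned by
#' [landCoverCodes()].
#'
#' @export
setClass("LandCoverRaster", contains = "GridLayer")

setValidity("LandCoverRaster", function(object) {
  v <- object@values[!is.na(object@values)]
  if (length(v) && !all(v %in% .LAND_COVER_CODES))
    return("land-cover values must be codes from landCoverCodes()")
  TRUE
})

#' PopulationRaster: population counts per cell
#'
#' Non-negative real counts (persons per cell); here, adults aged 60+ on a
#' 1-km grid.
#'
#' @export
setClass("PopulationRaster", contains = "GridLayer")

setValidity("PopulationRaster", function(object) {
  v <- object@values[!is.na(object@values)]
  if (length(v) && any(v < 0)) return("population counts must be >= 0")
  TRUE
})

#' FrictionSurface: traversal speed per cell
#'
#' `values` holds speed in km/h; barrier cells (open water with no bridging
#' road) are `NA` in `values` and `TRUE` in `barrierMask`. Every non-barrier
#' cell has a strictly positive speed.
#'
#' @slot barrierMask logical matrix, `TRUE` where the cell is untraversable.
#' @export
setClass("FrictionSurface", contains = "GridLayer",
         representation(barrierMask = "matrix"))

setValidity("FrictionSurface", function(object) {
  if (!identical(dim(object@barrierMask), dim(object@values)))
    return("barrierMask must have the same dimensions as values")
  sp <- object@values[!object@barrierMask]
  if (length(sp) && any(is.na(sp) | sp <= 0))
    return("non-barrier cells must have a finite positive speed")
  if (any(!is.na(object@values[object@barrierMask])))
    return("barrier cells must have NA speed")
  TRUE
})

#' TravelTimeRaster: minutes to the nearest target facility
#'
#' Minutes are non-negative; `Inf` marks cells with no barrier-free path to
#' any facility (unreachable); `NA` marks nodata.
#'
#' @export
setClass("TravelTimeRaster", contains = "GridLayer")

setValidity("TravelTimeRaster", function(object) {
  v <- object@values[!is.na(object@values)]
  if (length(v) && any(v < 0)) return("travel times must be >= 0")
  TRUE
})

#' RoadNetwork: classified polyline road segments
#'
#' @slot segments list; each element is `list(coords=, class=)` where
#'   `coords` is an n x 2 matrix of planar vertices (metres, n >= 2) and
#'   `class` is one of [roadClasses()].
#' @export
setClass("RoadNetwork", representation(segments = "list"))

setValidity("RoadNetwork", function(object) {
  for (s in object@segments) {
    if (!is.list(s) || is.null(s$coords) || is.null(s$class))
      return("each segment needs $coords and $class")
    if (!is.matrix(s$coords) || ncol(s$coords) != 2 || nrow(s$coords) < 2)
      return("segment coords must be an n x 2 matrix with n >= 2")
    if (!(s$class %in% .ROAD_CLASSES))
      return(sprintf("unknown road class '%s'", s$class))
  }
  TRUE
})

#' roadNetwork constructor
#' @param segments list of `list(coords, class)` segments.
#' @return A [RoadNetwork-class].
#' @export
roadNetwork <- function(segments = list()) new("RoadNetwork", segments = segments)

#' SpeedTable: travel speed by surface/road class
#'
#' Houses the model's speed parameters: km/h per land-cover or road class,
#' plus the classes treated as absolute travel barriers.
#'
#' @slot speeds named numeric vector, km/h, all strictly positive.
#' @slot barriers character vector of class names with no finite speed.
#' @export
setClass("SpeedTable",
         representation(speeds = "numeric", barriers = "character"))

setValidity("SpeedTable", function(object) {
  if (is.null(names(object@speeds)) || any(!nzchar(names(object@speeds))))
    return("speeds must be a named vector")
  if (any(!is.finite(object@speeds) | object@speeds <= 0))
    return("all non-barrier speeds must be finite and > 0")
  if (any(object@barriers %in% names(object@speeds)))
    return("a class cannot be both a barrier and carry a speed")
  TRUE
})

#' Default speed table
#'
#' Motorways/primary roads 100 km/h, secondary roads 50 km/h, tertiary roads
#' 30 km/h; barren land and built-up areas a 5 km/h and forests a 2 km/h
#' walking speed; open water is a barrier to any kind of travel.
#'
#' @param speeds optional named numeric overriding individual defaults (km/h).
#' @param barriers classes treated as untraversable.
#' @return A [SpeedTable-class].
#' @examples
#' defaultSpeedTable()
#' defaultSpeedTable(speeds = c(TERTIARY = 20))
#' @export
defaultSpeedTable <- function(speeds = numeric(), barriers = "WATER") {
  base <- c(PRIMARY = 100, SECONDARY = 50, TERTIARY = 30,
            BARREN = 5, BUILT_UP = 5, FOREST = 2)
  if (length(speeds)) base[names(speeds)] <- speeds
  new("SpeedTable", speeds = base, barriers = barriers)
}

#' FacilitySet: healthcare facility point records
#'
#' A set of facility records pooled from up to two registries (OSM, MFL).
#' Each record has a unique id, planar coordinates, a source registry, the
#' raw facility type string and the derived hospital flag.
#'
#' @slot records data.frame with columns id, x, y, source, raw_type,
#'   is_hospital.
#' @export
setClass("FacilitySet", representation(records = "data.frame"))

setValidity("FacilitySet", function(object) {
  r <- object@records
  need <- c("id", "x", "y", "source", "raw_type", "is_hospital")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(r$id)) return("facility ids must be unique within a set")
  if (nrow(r) && !all(r$source %in% .FACILITY_SOURCES))
    return("source must be 'OSM' or 'MFL'")
  TRUE
})

#' CutoffScheme: ordered travel-time category boundaries
#'
#' Boundaries in minutes, strictly increasing and positive. Boundaries
#' `b1 < b2 < b3` define categories `[0,b1)`, `[b1,b2)`, `[b2,b3)` and
#' `[b3, Inf]`; a value falling exactly on a boundary belongs to the higher
#' category (closed-left intervals).
#'
#' @slot boundaries numeric vector of boundaries in minutes.
#' @slot labels character vector of `length(boundaries)+1` category labels.
#' @export
setClass("CutoffScheme",
         representation(boundaries = "numeric", labels = "character"))

setValidity("CutoffScheme", function(object) {
  b <- object@boundaries
  if (!length(b) || any(b <= 0) || any(diff(b) <= 0))
    return("boundaries must be positive and strictly increasing")
  if (length(object@labels) != length(b) + 1L)
    return("need one more label than boundaries")
  TRUE
})

#' Cut-off schemes for hospital and any-facility travel time
#'
#' `hospitalCutoffs()` categorises hospital travel time as <2 h, 2-6 h,
#' 6-12 h and >12 h (boundaries 120/360/720 min). `anyFacilityCutoffs()`
#' categorises any-facility travel time as <1 h, 1-2 h, 2-6 h and >6 h
#' (boundaries 60/120/360 min).
#'
#' @return A [CutoffScheme-class].
#' @export
hospitalCutoffs <- function()
  new("CutoffScheme", boundaries = c(120, 360, 720),
      labels = c("<2h", "2-6h", "6-12h", ">12h"))

#' @rdname hospitalCutoffs
#' @export
anyFacilityCutoffs <- function()
  new("CutoffScheme", boundaries = c(60, 120, 360),
      labels = c("<1h", "1-2h", "2-6h", ">6h"))

#' SyntheticScenario: parameters of the synthetic landscape generator
#'
#' @slot seed integer master seed; all generator randomness derives from it.
#' @slot nSettlements number of settlement centres.
#' @slot settlementSpread Gaussian scale (metres) of population and facility
#'   placement around settlement centres.
#' @slot facilityCounts data.frame with columns source, type, n giving the
#'   number of facilities requested per registry and raw type.
#' @slot waterFraction,forestFraction target fractions of the landscape.
#' @slot duplicateFraction fraction of MFL facilities duplicated into the OSM
#'   registry with small coordinate jitter (registries overlap but are never
#'   deduplicated downstream).
#' @slot totalPopulation total adults aged 60+ across the landscape.
#' @export
setClass("SyntheticScenario",
  representation(seed = "integer", nSettlements = "integer",
                 settlementSpread = "numeric", facilityCounts = "data.frame",
                 waterFraction = "numeric", forestFraction = "numeric",
                 duplicateFraction = "numeric", totalPopulation = "numeric"))

setValidity("SyntheticScenario", function(object) {
  msgs <- character()
  if (object@nSettlements < 1L) msgs <- c(msgs, "need at least one settlement")
  fr <- c(object@waterFraction, object@forestFraction)
  if (any(fr < 0 | fr > 1)) msgs <- c(msgs, "fractions must lie in [0,1]")
  if (sum(fr) > 1) msgs <- c(msgs, "landscape fractions must sum to <= 1")
  if (object@duplicateFraction < 0 || object@duplicateFraction > 1)
    msgs <- c(msgs, "duplicateFraction must lie in [0,1]")
  if (object@totalPopulation < 0) msgs <- c(msgs, "totalPopulation must be >= 0")
  fc <- object@facilityCounts
  if (!all(c("source", "type", "n") %in% names(fc)))
    msgs <- c(msgs, "facilityCounts needs columns source, type, n")
  else if (nrow(fc) && any(fc$n < 0))
    msgs <- c(msgs, "facility counts must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a synthetic scenario
#'
#' Defaults describe a 50 km x 50 km rural landscape: eight settlements, a
#' spanning-tree road network, two facility registries that partially overlap,
#' ten percent open water, twenty percent forest, and 50,000 adults aged 60+
#' clustered around the settlements.
#'
#' @param seed integer master seed.
#' @param nSettlements number of settlement centres.
#' @param settlementSpread kernel scale in metres.
#' @param facilityCounts data.frame(source, type, n).
#' @param waterFraction,forestFraction landscape fractions in `[0,1]`.
#' @param duplicateFraction cross-registry duplication fraction.
#' @param totalPopulation total population (adults 60+).
#' @return A [SyntheticScenario-class].
#' @examples
#' sc <- syntheticScenario(seed = 1, nSettlements = 5)
#' @export
syntheticScenario <- function(seed = 1L, nSettlements = 8L,
                              settlementSpread = 3000,
                              facilityCounts = data.frame(
                                source = c("MFL", "MFL", "OSM", "OSM"),
                                type = c("hospital", "clinic", "hospital",
                                         "doctors"),
                                n = c(4L, 14L, 3L, 8L),
                                stringsAsFactors = FALSE),
                              waterFraction = 0.10, forestFraction = 0.20,
                              duplicateFraction = 0.25,
                              totalPopulation = 50000) {
  new("SyntheticScenario", seed = as.integer(seed),
      nSettlements = as.integer(nSettlements),
      settlementSpread = as.numeric(settlementSpread),
      facilityCounts = facilityCounts,
      waterFraction = as.numeric(waterFraction),
      forestFraction = as.numeric(forestFraction),
      duplicateFraction = as.numeric(duplicateFraction),
      totalPopulation = as.numeric(totalPopulation))
}

#' AccessSummary: population-weighted accessibility summary
#'
#' One row per region: population total, per-category population shares,
#' proportion above the headline cut-off with Wilson interval, worst-quintile
#' weighted median and IQR of travel time, and the unreachable share.
#'
#' @slot table data.frame of per-region statistics.
#' @slot scheme the [CutoffScheme-class] used.
#' @slot cutoff headline cut-off in minutes.
#' @export
setClass("AccessSummary",
         representation(table = "data.frame", scheme = "CutoffScheme",
                        cutoff = "numeric"))
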