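#' @include AllClasses.R
NULL

#' Grid accessors
#'
#' @param x a [GridSpec-class] or [GridLayer-class].
#' @return `nRows`/`nCols` the grid dimensions, `cellSize` the cell edge in
#'   metres, `gridSpecOf` the layer's [GridSpec-class], `rasterValues` the
#'   underlying matrix.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))
#' @rdname grid-accessors
#' @export
setGeneric("nCols", function(x) standardGeneric("nCols"))
#' @rdname grid-accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname grid-accessors
#' @export
setGeneric("gridSpecOf", function(x) standardGeneric("gridSpecOf"))
#' @rdname grid-accessors
#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' @rdname grid-accessors
setMethod("nRows", "GridSpec", function(x) x@nRows)
#' @rdname grid-accessors
setMethod("nCols", "GridSpec", function(x) x@nCols)
#' @rdname grid-accessors
setMethod("cellSize", "GridSpec", function(x) x@cellSize)
#' @rdname grid-accessors
setMethod("nRows", "GridLayer", function(x) x@grid@nRows)
#' @rdname grid-accessors
setMethod("nCols", "GridLayer", function(x) x@grid@nCols)
#' @rdname grid-accessors
setMethod("cellSize", "GridLayer", function(x) x@grid@cellSize)
#' @rdname grid-accessors
setMethod("gridSpecOf", "GridLayer", function(x) x@grid)
#' @rdname grid-accessors
setMethod("rasterValues", "GridLayer", function(x) x@values)

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %g m, origin (%g, %g)\n",
              object@nRows, object@nCols, object@cellSize,
              object@originX, object@originY))
})

setMethod("show", "GridLayer", function(object) {
  v <- object@values
  fin <- v[is.finite(v)]
  cat(sprintf("%s: %d x %d @ %g m", class(object), nrow(v), ncol(v),
              object@grid@cellSize))
  if (length(fin))
    cat(sprintf(" | finite range [%g, %g]", min(fin), max(fin)))
  cat(sprintf(" | %d NA, %d Inf\n", sum(is.na(v)),
              sum(is.infinite(v) & !is.na(v))))
})

#' Are two grids identical?
#'
#' Layers are combinable only when their grid definitions match exactly
#' (dimensions, cell size and origin).
#'
#' @param a,b [GridSpec-class] objects.
#' @return TRUE/FALSE.
#' @export
sameGrid <- function(a, b) {
  isTRUE(all.equal(c(a@nRows, a@nCols, a@cellSize, a@originX, a@originY),
                   c(b@nRows, b@nCols, b@cellSize, b@originX, b@originY)))
}

.stopIfGridMismatch <- function(a, b, what = "layers") {
  if (!sameGrid(a, b))
    stop(what, " must share an identical grid definition", call. = FALSE)
  invisible(TRUE)
}

#' Grid extent
#'
#' @param grid a [GridSpec-class].
#' @return Named numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @export
gridExtent <- function(grid) {
  c(xmin = grid@originX,
    xmax = grid@originX + grid@nCols * grid@cellSize,
    ymin = grid@originY - grid@nRows * grid@cellSize,
    ymax = grid@originY)
}

#' Cell index from planar coordinates
#'
#' Points on the right/bottom edge of the extent are assigned to the last
#' column/row so that the closed extent maps onto valid cells.
#'
#' @param grid a [GridSpec-class].
#' @param x,y planar coordinates in metres (vectorised).
#' @return data.frame with columns `row`, `col`; NA outside the extent.
#' @export
cellFromXY <- function(grid, x, y) {
  col <- floor((x - grid@originX) / grid@cellSize) + 1
  row <- floor((grid@originY - y) / grid@cellSize) + 1
  col[x == grid@originX + grid@nCols * grid@cellSize] <- grid@nCols
  row[y == grid@originY - grid@nRows * grid@cellSize] <- grid@nRows
  bad <- col < 1 | col > grid@nCols | row < 1 | row > grid@nRows
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Cell-centre coordinates
#'
#' @param grid a [GridSpec-class].
#' @param row,col cell indices (vectorised).
#' @return data.frame with planar `x`, `y` of cell centres in metres.
#' @export
xyFromCell <- function(grid, row, col) {
  data.frame(x = grid@originX + (col - 0.5) * grid@cellSize,
             y = grid@originY - (row - 0.5) * grid@cellSize)
}

#' Coarse grid nested in a fine grid
#'
#' Builds the coarse [GridSpec-class] whose cells tile the fine grid in
#' `factor` x `factor` blocks; the fine grid dimensions must be exact
#' multiples of `factor`.
#'
#' @param grid fine [GridSpec-class].
#' @param factor integer aggregation factor (e.g. 10 for 100 m to 1 km).
#' @return The nested coarse [GridSpec-class].
#' @export
coarsenGrid <- function(grid, factor = 10L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (grid@nRows %% factor != 0L || grid@nCols %% factor != 0L)
    stop(sprintf("grid dimensions (%d x %d) are not multiples of factor %d",
                 grid@nRows, grid@nCols, factor), call. = FALSE)
  gridSpec(grid@nRows %/% factor, grid@nCols %/% factor,
           cellSize = grid@cellSize * factor,
           originX = grid@originX, originY = grid@originY,
           nodata = grid@nodata)
}

## check fine grid nests exactly in coarse grid; returns block factor
.nestingFactor <- function(fine, coarse) {
  f <- coarse@cellSize / fine@cellSize
  if (abs(f - round(f)) > 1e-9)
    stop("grids do not nest: cell sizes are not an integer multiple",
         call. = FALSE)
  f <- as.integer(round(f))
  ok <- fine@nRows == coarse@nRows * f && fine@nCols == coarse@nCols * f &&
    isTRUE(all.equal(fine@originX, coarse@originX)) &&
    isTRUE(all.equal(fine@originY, coarse@originY))
  if (!ok) stop("grids do not nest: extents or origins differ", call. = FALSE)
  f
}
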