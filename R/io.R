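#' @include AllClasses.R grid.R friction.R stats.R
NULL

## Unreachable travel time is written as -1 (documented sentinel); nodata as
## the grid's nodata value. Both are restored on read.
.UNREACHABLE_ON_DISK <- -1

#' Write a raster layer as an Esri ASCII grid
#'
#' Plain-text georeferenced raster: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of cell
#' values from the top row down. `NA` cells are written as the nodata value;
#' `Inf` travel times (unreachable) as `-1`. Values are written with 10
#' significant digits, enough to round-trip the statistics reported here.
#'
#' @param layer a [GridLayer-class].
#' @param path output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(layer, path) {
  g <- layer@grid
  v <- layer@values
  v[is.na(v)] <- g@nodata
  v[is.infinite(v)] <- .UNREACHABLE_ON_DISK
  hdr <- c(sprintf("ncols %d", g@nCols),
           sprintf("nrows %d", g@nRows),
           sprintf("xllcorner %.10g", g@originX),
           sprintf("yllcorner %.10g", g@originY - g@nRows * g@cellSize),
           sprintf("cellsize %.10g", g@cellSize),
           sprintf("NODATA_value %.10g", g@nodata))
  body <- apply(v, 1, function(r) paste(formatC(r, format = "g", digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an Esri ASCII grid
#'
#' @param path file written by [writeAsciiGrid()] (or any Esri ASCII grid).
#' @param layerClass the [GridLayer-class] subclass to construct; for
#'   `"TravelTimeRaster"` the `-1` sentinel is restored to `Inf`.
#' @return A layer of class `layerClass`.
#' @export
readAsciiGrid <- function(path, layerClass = "TravelTimeRaster") {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- tolower(vapply(hdr, `[`, "", 1L))
  val <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(val) <- key
  nc <- as.integer(val[["ncols"]]); nr <- as.integer(val[["nrows"]])
  cs <- val[["cellsize"]]
  g <- gridSpec(nr, nc, cellSize = cs, originX = val[["xllcorner"]],
                originY = val[["yllcorner"]] + nr * cs,
                nodata = val[["nodata_value"]])
  v <- matrix(scan(text = paste(lines[-(1:6)], collapse = "\n"),
                   quiet = TRUE), nrow = nr, ncol = nc, byrow = TRUE)
  v[v == g@nodata] <- NA
  if (layerClass == "TravelTimeRaster") v[!is.na(v) & v == .UNREACHABLE_ON_DISK] <- Inf
  if (layerClass == "LandCoverRaster") storage.mode(v) <- "integer"
  new(layerClass, grid = g, values = v)
}

#' Write facilities as GeoJSON
#'
#' Point FeatureCollection with properties id, source, raw_type,
#' is_hospital; coordinates are the planar metres of the analysis grid.
#'
#' @param facilities a [FacilitySet-class].
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
writeFacilitiesGeoJSON <- function(facilities, path) {
  r <- facilities@records
  feats <- lapply(seq_len(nrow(r)), function(k) list(
    type = "Feature",
    geometry = list(type = "Point", coordinates = c(r$x[k], r$y[k])),
    properties = list(id = r$id[k], source = r$source[k],
                      raw_type = r$raw_type[k],
                      is_hospital = r$is_hospital[k])))
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read facilities from GeoJSON or CSV
#'
#' GeoJSON must be a Point FeatureCollection with the properties written by
#' [writeFacilitiesGeoJSON()]; CSV must have columns id, x, y, source,
#' raw_type (is_hospital optional, derived via [classifyFacility()] when
#' absent).
#'
#' @param path input file; format chosen by extension.
#' @return A [FacilitySet-class].
#' @export
readFacilities <- function(path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    fc <- jsonlite::read_json(path)
    rec <- do.call(rbind, lapply(fc$features, function(f) data.frame(
      id = f$properties$id,
      x = as.numeric(f$geometry$coordinates[[1]]),
      y = as.numeric(f$geometry$coordinates[[2]]),
      source = f$properties$source, raw_type = f$properties$raw_type,
      is_hospital = as.logical(f$properties$is_hospital),
      stringsAsFactors = FALSE)))
    return(new("FacilitySet", records = rec))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(df$is_hospital)) df$is_hospital <- classifyFacility(df$raw_type)
  facilitySet(df$id, df$x, df$y, df$source, df$raw_type, df$is_hospital)
}

#' Write facilities as CSV
#' @param facilities a [FacilitySet-class].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
writeFacilitiesCSV <- function(facilities, path) {
  utils::write.csv(facilities@records, path, row.names = FALSE)
  invisible(path)
}

#' Write a road network as GeoJSON
#'
#' LineString FeatureCollection with a `class` property per segment.
#'
#' @param roads a [RoadNetwork-class].
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
writeRoadsGeoJSON <- function(roads, path) {
  feats <- lapply(roads@segments, function(s) list(
    type = "Feature",
    geometry = list(type = "LineString",
                    coordinates = lapply(seq_len(nrow(s$coords)),
                                         function(i) s$coords[i, ])),
    properties = list(class = s$class)))
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a road network from GeoJSON
#' @param path a LineString FeatureCollection written by
#'   [writeRoadsGeoJSON()] (or equivalent).
#' @return A [RoadNetwork-class].
#' @export
readRoadsGeoJSON <- function(path) {
  fc <- jsonlite::read_json(path)
  segs <- lapply(fc$features, function(f) {
    coords <- do.call(rbind, lapply(f$geometry$coordinates,
                                    function(p) as.numeric(unlist(p))))
    list(coords = coords, class = f$properties$class)
  })
  roadNetwork(segs)
}

#' Write / read a speed table as YAML
#'
#' @param speeds a [SpeedTable-class].
#' @param path `.yaml` path.
#' @return `writeSpeedTableYAML`: `path` invisibly; `readSpeedTableYAML`:
#'   a [SpeedTable-class].
#' @export
writeSpeedTableYAML <- function(speeds, path) {
  yaml::write_yaml(list(speeds_kmh = as.list(speeds@speeds),
                        barriers = as.list(speeds@barriers)), path)
  invisible(path)
}

#' @rdname writeSpeedTableYAML
#' @export
readSpeedTableYAML <- function(path) {
  y <- yaml::read_yaml(path)
  new("SpeedTable", speeds = unlist(y$speeds_kmh),
      barriers = as.character(unlist(y$barriers)))
}
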