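#' @include AllClasses.R grid.R synthetic.R facilities.R friction.R
#' @include traveltime.R stats.R io.R
NULL

#' Pipeline configuration
#'
#' Exactly one of `scenario` (synthetic world) or `inputs` (paths to
#' pre-built files: `landcover` ASCII grid, `roads` GeoJSON, `facilities`
#' GeoJSON/CSV, `population` ASCII grid) must be supplied.
#'
#' @param scenario a [SyntheticScenario-class], or `NULL`.
#' @param inputs named list of input file paths, or `NULL`.
#' @param nRows,nCols model grid dimensions (100 m cells; multiples of
#'   `aggFactor`), used for the synthetic branch.
#' @param cellSize model cell size in metres.
#' @param aggFactor aggregation factor from the model grid to the population
#'   grid (10: 100 m to 1 km).
#' @param speeds a [SpeedTable-class].
#' @param aggregation block statistic for [aggregateTravelTime()].
#' @param cutoffHospital,cutoffAny headline cut-offs in minutes for the
#'   hospital and any-facility summaries.
#' @param wilsonN Wilson denominator policy (`NULL`: populated cells).
#' @param outDir output directory (created if missing).
#' @param seed integer; overrides the scenario seed when supplied.
#' @return A validated `geoaccess_config` list.
#' @export
pipelineConfig <- function(scenario = NULL, inputs = NULL,
                           nRows = 300L, nCols = 300L, cellSize = 100,
                           aggFactor = 10L, speeds = defaultSpeedTable(),
                           aggregation = "mean", cutoffHospital = 360,
                           cutoffAny = 120, wilsonN = NULL,
                           outDir = tempfile("geoaccess_"), seed = NULL) {
  if (is.null(scenario) == is.null(inputs))
    stop("supply exactly one of 'scenario' or 'inputs'", call. = FALSE)
  if (!is.null(inputs)) {
    need <- c("landcover", "roads", "facilities", "population")
    miss <- setdiff(need, names(inputs))
    if (length(miss))
      stop("inputs must name: ", paste(miss, collapse = ", "), call. = FALSE)
    gone <- !vapply(unlist(inputs[need]), file.exists, logical(1))
    if (any(gone))
      stop("input file(s) not found: ",
           paste(unlist(inputs[need])[gone], collapse = ", "), call. = FALSE)
  }
  if (!is.null(scenario)) {
    if (!is.null(seed)) scenario@seed <- as.integer(seed)
    validObject(scenario)
    if (nRows %% aggFactor || nCols %% aggFactor)
      stop("model grid dimensions must be multiples of aggFactor",
           call. = FALSE)
  }
  structure(list(scenario = scenario, inputs = inputs, nRows = nRows,
                 nCols = nCols, cellSize = cellSize, aggFactor = aggFactor,
                 speeds = speeds, aggregation = aggregation,
                 cutoffHospital = cutoffHospital, cutoffAny = cutoffAny,
                 wilsonN = wilsonN, outDir = outDir),
            class = "geoaccess_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror [pipelineConfig()] arguments; `scenario:` holds
#' [syntheticScenario()] fields (with `facility_counts:` a list of
#' `{source, type, n}` entries); `speeds:` holds `speeds_kmh` and `barriers`.
#'
#' @param path `.yaml` config path.
#' @return A `geoaccess_config` list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  scenario <- NULL
  if (!is.null(y$scenario)) {
    s <- y$scenario
    fc <- if (is.null(s$facility_counts)) formals(syntheticScenario)$facilityCounts
          else do.call(rbind, lapply(s$facility_counts, as.data.frame))
    scenario <- syntheticScenario(
      seed = s$seed %||% 1L, nSettlements = s$n_settlements %||% 8L,
      settlementSpread = s$settlement_spread %||% 3000,
      facilityCounts = if (is.data.frame(fc)) fc else eval(fc),
      waterFraction = s$water_fraction %||% 0.10,
      forestFraction = s$forest_fraction %||% 0.20,
      duplicateFraction = s$duplicate_fraction %||% 0.25,
      totalPopulation = s$total_population %||% 50000)
  }
  speeds <- if (is.null(y$speeds)) defaultSpeedTable()
            else new("SpeedTable", speeds = unlist(y$speeds$speeds_kmh),
                     barriers = as.character(unlist(y$speeds$barriers)))
  pipelineConfig(scenario = scenario, inputs = y$inputs,
                 nRows = y$n_rows %||% 300L, nCols = y$n_cols %||% 300L,
                 cellSize = y$cell_size %||% 100,
                 aggFactor = y$agg_factor %||% 10L, speeds = speeds,
                 aggregation = y$aggregation %||% "mean",
                 cutoffHospital = y$cutoff_hospital %||% 360,
                 cutoffAny = y$cutoff_any %||% 120,
                 wilsonN = y$wilson_n,
                 outDir = y$out_dir %||% tempfile("geoaccess_"),
                 seed = y$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the accessibility pipeline end to end
#'
#' Generates (or reads) the landscape, builds the friction surface, computes
#' travel time to the nearest hospital and to the nearest facility of any
#' type, aggregates both to the population grid, and writes all artifacts
#' (ASCII grid rasters, facilities GeoJSON+CSV, summary CSV) to
#' `config$outDir`. The run is fully reproducible from the configuration:
#' the same config and seed yield byte-identical summary CSVs.
#'
#' @param config a `geoaccess_config` from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @param writeRasters logical; write the raster artifacts (the summary CSV
#'   is always written).
#' @param verbose logical; log stage progress.
#' @return Invisibly, a list with the facility set, friction surface, 100 m
#'   and 1 km travel-time rasters (hospital, any), population raster and the
#'   two [AccessSummary-class] objects.
#' @export
runPipeline <- function(config, writeRasters = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "geoaccess_config"))
  log <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)

  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$scenario)) {
      log("[simulate] synthetic landscape, seed %d", config$scenario@seed)
      grid <- gridSpec(config$nRows, config$nCols, cellSize = config$cellSize)
      land <- generateLandscape(config$scenario, grid)
      landcover <- land$landcover; roads <- land$roads
      grid1km <- coarsenGrid(grid, config$aggFactor)
      pop <- generatePopulation(config$scenario, landcover, grid1km)
      facilities <- generateFacilities(config$scenario, landcover)
    } else {
      log("[read] %s", config$inputs$landcover)
      landcover <- readAsciiGrid(config$inputs$landcover, "LandCoverRaster")
      roads <- readRoadsGeoJSON(config$inputs$roads)
      facilities <- readFacilities(config$inputs$facilities)
      pop <- readAsciiGrid(config$inputs$population, "PopulationRaster")
      grid <- landcover@grid
      grid1km <- pop@grid
      .nestingFactor(grid, grid1km)
    }

    stage <- "friction"
    log("[friction] rasterizing %d road segments", length(roads@segments))
    roadRaster <- rasterizeRoads(roads, grid)
    friction <- buildFriction(landcover, roadRaster, config$speeds)

    stage <- "traveltime"
    log("[traveltime] cost distance: hospitals, then any facility")
    ttHosp <- travelTimeTo(friction, facilities, "hospital")
    ttAny <- travelTimeTo(friction, facilities, "any")
    ttHosp1km <- aggregateTravelTime(ttHosp, grid1km, config$aggregation)
    ttAny1km <- aggregateTravelTime(ttAny, grid1km, config$aggregation)

    stage <- "summarize"
    sumHosp <- accessSummary(ttHosp1km, pop, hospitalCutoffs(),
                             cutoff = config$cutoffHospital,
                             wilsonN = config$wilsonN)
    sumAny <- accessSummary(ttAny1km, pop, anyFacilityCutoffs(),
                            cutoff = config$cutoffAny,
                            wilsonN = config$wilsonN)

    stage <- "write"
    .writeSummaryCSV(sumHosp, sumAny,
                     file.path(config$outDir, "summary.csv"))
    writeFacilitiesCSV(facilities,
                       file.path(config$outDir, "facilities.csv"))
    if (writeRasters) {
      writeAsciiGrid(landcover, file.path(config$outDir, "landcover.asc"))
      writeAsciiGrid(friction, file.path(config$outDir, "friction.asc"))
      writeAsciiGrid(ttHosp1km,
                     file.path(config$outDir, "traveltime_hospital_1km.asc"))
      writeAsciiGrid(ttAny1km,
                     file.path(config$outDir, "traveltime_any_1km.asc"))
      writeAsciiGrid(pop, file.path(config$outDir, "population.asc"))
      writeFacilitiesGeoJSON(facilities,
                             file.path(config$outDir, "facilities.geojson"))
      writeRoadsGeoJSON(roads, file.path(config$outDir, "roads.geojson"))
      writeSpeedTableYAML(config$speeds,
                          file.path(config$outDir, "speeds.yaml"))
    }
    log("[done] %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
    list(facilities = facilities, friction = friction,
         travelTimeHospital = ttHosp, travelTimeAny = ttAny,
         travelTimeHospital1km = ttHosp1km, travelTimeAny1km = ttAny1km,
         population = pop, summaryHospital = sumHosp, summaryAny = sumAny)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

## Deterministic summary CSV: fixed column order, fixed 12-significant-digit
## formatting, so identical runs are byte-identical.
.writeSummaryCSV <- function(sumHosp, sumAny, path) {
  fmt <- function(s, label) {
    tb <- s@table
    tb <- cbind(data.frame(target = label, stringsAsFactors = FALSE), tb)
    num <- vapply(tb, is.numeric, logical(1))
    tb[num] <- lapply(tb[num], function(v) formatC(v, format = "g",
                                                   digits = 12))
    tb
  }
  a <- fmt(sumHosp, "hospital"); b <- fmt(sumAny, "any")
  ## category share columns differ between schemes; align on union
  cols <- union(names(a), names(b))
  for (cl in setdiff(cols, names(a))) a[[cl]] <- ""
  for (cl in setdiff(cols, names(b))) b[[cl]] <- ""
  out <- rbind(a[cols], b[cols])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
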