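#' @include AllClasses.R
NULL

## OSM amenity/healthcare tag values and common MFL primary-care level
## designations accepted by the classifier.
.HOSPITAL_TYPES <- c("hospital")
.PRIMARY_TYPES <- c("clinic", "doctors", "health_centre", "health_center",
                    "health_post", "dispensary", "primary_care")

#' Classify a facility type string as hospital or primary care
#'
#' OSM facilities carry `hospital`, `clinic` or `doctors` tag values; MFL
#' inventories use primary-care level designations such as `health_centre`,
#' `health_post` or `dispensary`. Only `hospital` maps to the hospital class;
#' every other accepted value is primary care.
#'
#' @param raw_type character vector of raw type strings (case-insensitive).
#' @return Logical vector: `TRUE` for hospitals.
#' @examples
#' classifyFacility(c("hospital", "clinic", "doctors"))
#' @export
classifyFacility <- function(raw_type) {
  if (!length(raw_type) || any(!nzchar(raw_type)) || anyNA(raw_type))
    stop("raw_type must be non-empty", call. = FALSE)
  t <- tolower(raw_type)
  known <- c(.HOSPITAL_TYPES, .PRIMARY_TYPES)
  bad <- setdiff(unique(t), known)
  if (length(bad))
    stop(sprintf("unknown facility type(s) %s; accepted values: %s",
                 paste0("'", bad, "'", collapse = ", "),
                 paste(known, collapse = ", ")), call. = FALSE)
  t %in% .HOSPITAL_TYPES
}

#' Construct a FacilitySet
#'
#' @param id,x,y,source,raw_type vectors of equal length; `is_hospital` is
#'   derived from `raw_type` via [classifyFacility()] unless supplied.
#' @param is_hospital optional logical override (e.g. for MFL inventories
#'   whose hospital flag is inherited from the source rather than re-derived).
#' @return A [FacilitySet-class].
#' @export
facilitySet <- function(id, x, y, source, raw_type,
                        is_hospital = classifyFacility(raw_type)) {
  df <- data.frame(id = as.character(id), x = as.numeric(x),
                   y = as.numeric(y), source = as.character(source),
                   raw_type = as.character(raw_type),
                   is_hospital = as.logical(is_hospital),
                   stringsAsFactors = FALSE)
  new("FacilitySet", records = df)
}

#' Facility set accessors and filters
#'
#' `facilityRecords` returns the underlying data.frame; `nFacilities` the
#' record count; `hospitalsOnly` the pure subset of hospital records;
#' `facilitiesOfSource` the pure subset from one registry.
#'
#' @param x a [FacilitySet-class].
#' @param source registry name, `"OSM"` or `"MFL"`.
#' @name facility-accessors
NULL

#' @rdname facility-accessors
#' @export
setGeneric("facilityRecords", function(x) standardGeneric("facilityRecords"))
#' @rdname facility-accessors
setMethod("facilityRecords", "FacilitySet", function(x) x@records)

#' @rdname facility-accessors
#' @export
setGeneric("nFacilities", function(x) standardGeneric("nFacilities"))
#' @rdname facility-accessors
setMethod("nFacilities", "FacilitySet", function(x) nrow(x@records))

#' @rdname facility-accessors
#' @export
hospitalsOnly <- function(x) {
  new("FacilitySet", records = x@records[x@records$is_hospital, , drop = FALSE])
}

#' @rdname facility-accessors
#' @export
facilitiesOfSource <- function(x, source) {
  new("FacilitySet",
      records = x@records[x@records$source == source, , drop = FALSE])
}

setMethod("show", "FacilitySet", function(object) {
  r <- object@records
  cat(sprintf("FacilitySet: %d facilities (%d hospitals) | OSM %d, MFL %d\n",
              nrow(r), sum(r$is_hospital), sum(r$source == "OSM"),
              sum(r$source == "MFL")))
})

#' Pool two facility registries without deduplication
#'
#' The union keeps every record from both registries: the same physical
#' facility listed in both (even at slightly different coordinates) appears
#' twice. Nearest-facility travel time is unaffected by exact duplicates,
#' and deliberately no attempt is made to decide which near-coincident
#' records are the same facility. Ids are namespaced by source so the pooled
#' set keeps unique ids.
#'
#' @param osm,mfl [FacilitySet-class] objects.
#' @return The pooled [FacilitySet-class] with
#'   `nFacilities(osm) + nFacilities(mfl)` records.
#' @export
poolRegistries <- function(osm, mfl) {
  a <- osm@records; b <- mfl@records
  pool <- rbind(a, b)
  if (anyDuplicated(pool$id))
    pool$id <- paste(pool$source, pool$id, sep = ":")
  if (anyDuplicated(pool$id))  # same id twice within one source
    pool$id <- make.unique(pool$id, sep = "#")
  rownames(pool) <- NULL
  new("FacilitySet", records = pool)
}

#' Count cross-registry facility pairs within a radius
#'
#' Diagnostic for registry overlap: number of (OSM, MFL) record pairs lying
#' within `radius` metres of each other. Purely informational; the analysis
#' set is never deduplicated.
#'
#' @param x a pooled [FacilitySet-class].
#' @param radius metres.
#' @return Integer count of cross-source pairs.
#' @export
countCrossSourcePairs <- function(x, radius = 100) {
  r <- x@records
  a <- r[r$source == "OSM", ]; b <- r[r$source == "MFL", ]
  if (!nrow(a) || !nrow(b)) return(0L)
  d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2
  sum(d2 <= radius^2)
}

#' Facility density per 100,000 population
#'
#' @param count facility count (>= 0).
#' @param population population denominator (> 0), in persons.
#' @return `1e5 * count / population`. Reported tables round to 3 decimals.
#' @examples
#' round(facilityDensity(14, 20829000), 3)  # 0.067
#' @export
facilityDensity <- function(count, population) {
  if (any(population <= 0)) stop("population must be > 0", call. = FALSE)
  if (any(count < 0)) stop("count must be >= 0", call. = FALSE)
  1e5 * count / population
}

#' Per-region facility density table
#'
#' Cross-tabulates a facility set by region, source registry and facility
#' class (primary care, hospital, total) and attaches densities per 100,000
#' population. Region assignment is by point-in-polygon against the supplied
#' region polygons; facilities outside every polygon are counted in no region
#' and reported via a warning.
#'
#' @param facilities a [FacilitySet-class].
#' @param populations named numeric: population per region (persons).
#' @param regions optional named list of polygons (n x 2 coordinate
#'   matrices); when `NULL` all facilities fall in one region named after
#'   `names(populations)[1]`.
#' @return data.frame with columns region, source, facility_class, count,
#'   population, density_per_100k.
#' @export
densityTable <- function(facilities, populations, regions = NULL) {
  r <- facilities@records
  if (is.null(regions)) {
    region <- rep(names(populations)[1], nrow(r))
  } else {
    region <- assignRegions(r$x, r$y, regions)
    lost <- sum(is.na(region))
    if (lost > 0)
      warning(sprintf("%d facilities fall outside all region polygons %s",
                      lost, "and are counted in no region"), call. = FALSE)
  }
  rows <- list()
  for (reg in names(populations)) {
    inReg <- !is.na(region) & region == reg
    for (src in .FACILITY_SOURCES) {
      sel <- inReg & r$source == src
      nh <- sum(sel & r$is_hospital)
      np <- sum(sel & !r$is_hospital)
      pop <- populations[[reg]]
      for (cls in c("primary", "hospital", "total")) {
        cnt <- switch(cls, primary = np, hospital = nh, total = np + nh)
        rows[[length(rows) + 1L]] <- data.frame(
          region = reg, source = src, facility_class = cls, count = cnt,
          population = pop,
          density_per_100k = facilityDensity(cnt, pop),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign points to named regions by point-in-polygon
#'
#' Even-odd ray-casting test against each polygon in turn; a point on an
#' edge may be assigned to either adjacent region. Returns `NA` for points
#' in no polygon.
#'
#' @param x,y point coordinates (metres).
#' @param regions named list of n x 2 polygon coordinate matrices (closed or
#'   open rings).
#' @return Character vector of region names (or `NA`).
#' @export
assignRegions <- function(x, y, regions) {
  out <- rep(NA_character_, length(x))
  for (nm in names(regions)) {
    poly <- regions[[nm]]
    hit <- is.na(out) & .pointInPolygon(x, y, poly)
    out[hit] <- nm
  }
  out
}

## even-odd rule ray casting, vectorised over points
.pointInPolygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Reference facility-density table for sub-Saharan Africa
#'
#' Country-level counts of healthcare facilities (primary care, hospitals)
#' from the two registries (MFL inventory, OSM extract), total and 60+
#' populations in millions, and the published densities per 100,000 total
#' population, for 44 countries of sub-Saharan Africa. Used as a worked
#' example for the density arithmetic: density = 1e5 * count / population,
#' total = primary + hospital within each (country, source).
#'
#' @return data.frame with one row per country.
#' @examples
#' ref <- facilityDensityReference()
#' round(facilityDensity(ref$mfl_hospital[ref$country == "Burkina Faso"],
#'                       ref$pop_total_millions[ref$country == "Burkina Faso"]
#'                       * 1e6), 3)
#' @export
facilityDensityReference <- function() {
  utils::read.csv(system.file("extdata", "facility_density_table.csv",
                              package = "geoaccess"),
                  stringsAsFactors = FALSE, check.names = TRUE)
}
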