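#' @include AllClasses.R grid.R facilities.R
NULL

#' ProportionEstimate: a binomial proportion with Wilson interval
#'
#' @slot pHat point estimate.
#' @slot n effective denominator behind the interval.
#' @slot ciLow,ciHigh two-sided Wilson score interval bounds.
#' @slot z normal quantile used (1.959964 for 95%).
#' @export
setClass("ProportionEstimate",
         representation(pHat = "numeric", n = "numeric", ciLow = "numeric",
                        ciHigh = "numeric", z = "numeric"))

setValidity("ProportionEstimate", function(object) {
  ok <- object@ciLow >= -1e-12 && object@ciLow <= object@pHat + 1e-12 &&
    object@pHat <= object@ciHigh + 1e-12 && object@ciHigh <= 1 + 1e-12
  if (!ok) return("interval must satisfy 0 <= ciLow <= pHat <= ciHigh <= 1")
  TRUE
})

setMethod("show", "ProportionEstimate", function(object) {
  cat(sprintf("%.1f%% (95%% CI: %.1f%% - %.1f%%), n = %g\n",
              100 * object@pHat, 100 * object@ciLow, 100 * object@ciHigh,
              object@n))
})

#' Wilson score confidence interval for a binomial proportion
#'
#' Inverts the score test: centre `(p + z^2/2n) / (1 + z^2/n)`, half-width
#' `z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`, clipped to `[0, 1]`.
#' Well-behaved at proportions near 0 and 1, unlike the Wald interval.
#'
#' @param pHat proportion in `[0, 1]` (vectorised).
#' @param n effective sample size (> 0).
#' @param z normal quantile; 1.959964 gives two-sided 95% coverage.
#' @return matrix with columns `low`, `high`.
#' @examples
#' wilsonInterval(0, 100)   # upper bound z^2 / (n + z^2)
#' wilsonInterval(0.5, 50)  # symmetric about 0.5
#' @export
wilsonInterval <- function(pHat, n, z = 1.959964) {
  if (any(n <= 0)) stop("n must be > 0", call. = FALSE)
  if (any(pHat < 0 | pHat > 1)) stop("pHat must lie in [0, 1]", call. = FALSE)
  denom <- 1 + z^2 / n
  center <- (pHat + z^2 / (2 * n)) / denom
  half <- z * sqrt(pHat * (1 - pHat) / n + z^2 / (4 * n^2)) / denom
  ## clamp to [0,1] and guard containment of pHat against rounding
  cbind(low = pmin(pmax(0, center - half), pHat),
        high = pmax(pmin(1, center + half), pHat))
}

## shared: population-weighted share of cells with travel time above cutoff
.shareAbove <- function(t, w, cutoff) {
  keep <- !is.na(t) & !is.na(w)
  t <- t[keep]; w <- w[keep]
  W <- sum(w)
  if (W <= 0) stop("total population is zero", call. = FALSE)
  sum(w[t > cutoff]) / W  # Inf (unreachable) exceeds any cutoff
}

#' Population-weighted proportion with travel time above a cut-off
#'
#' Share of the population living in cells whose travel time exceeds
#' `cutoff` minutes; unreachable cells count as above any cut-off. A Wilson
#' score interval is attached using the explicit effective denominator `n`
#' (the choice of `n` is a reporting policy, not a property of the rasters;
#' see the package vignette).
#'
#' @param tt a [TravelTimeRaster-class] on the population grid.
#' @param pop a [PopulationRaster-class] on the same grid.
#' @param cutoff minutes (> 0).
#' @param n effective denominator for the Wilson interval; default: the
#'   number of populated cells (>= 1 person).
#' @param z normal quantile for the interval.
#' @return A [ProportionEstimate-class].
#' @export
proportionAbove <- function(tt, pop, cutoff, n = NULL, z = 1.959964) {
  .stopIfGridMismatch(tt@grid, pop@grid, "travel time and population")
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  p <- .shareAbove(as.vector(tt@values), as.vector(pop@values), cutoff)
  if (is.null(n)) n <- sum(pop@values >= 1, na.rm = TRUE)
  ci <- wilsonInterval(p, n, z)
  new("ProportionEstimate", pHat = p, n = as.numeric(n),
      ciLow = ci[1, "low"], ciHigh = ci[1, "high"], z = z)
}

#' Weighted quantile (midpoint cumulative-weight rule)
#'
#' Linear interpolation on the cumulative weight: observation i sits at
#' plotting position `(cumw_i - w_i/2) / sum(w)`; quantiles between positions
#' are interpolated linearly, and clamped to the extreme observations
#' outside. An interval with an infinite endpoint yields `Inf`.
#'
#' @param x values (may include `Inf` for unreachable).
#' @param w non-negative weights.
#' @param probs probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles.
#' @export
weightedQuantile <- function(x, w, probs) {
  keep <- !is.na(x) & !is.na(w) & w > 0
  x <- x[keep]; w <- w[keep]
  if (!length(x)) stop("no positive-weight observations", call. = FALSE)
  o <- order(x)
  x <- x[o]; w <- w[o]
  W <- sum(w)
  p <- (cumsum(w) - w / 2) / W
  vapply(probs, function(q) {
    if (q <= p[1]) return(x[1])
    if (q >= p[length(p)]) return(x[length(x)])
    hi <- which(p >= q)[1]
    lo <- hi - 1L
    if (is.infinite(x[hi]) || is.infinite(x[lo])) {
      if (p[lo] == q) return(x[lo])
      return(Inf)
    }
    x[lo] + (x[hi] - x[lo]) * (q - p[lo]) / (p[hi] - p[lo])
  }, numeric(1))
}

#' Weighted median and IQR of the worst travel-time band
#'
#' Sorts cells by travel time, restricts to the population-weighted band
#' `quantileBand` of the distribution (default the top fifth, `[0.8, 1]`,
#' splitting the boundary cell's weight so the band holds exactly the
#' requested population share), and returns the band's population-weighted
#' median and 25th/75th-percentile IQR in minutes. Unreachable cells sit at
#' `+Inf` at the top of the ordering by default; with enough unreachable
#' population the band statistics are themselves `Inf` (reported as
#' unreachable). Set `includeUnreachable = FALSE` to drop them first.
#'
#' @param tt a [TravelTimeRaster-class].
#' @param pop a [PopulationRaster-class] on the same grid.
#' @param quantileBand numeric length-2 within `[0, 1]`, low < high.
#' @param includeUnreachable logical.
#' @return list with `median`, `iqrLow`, `iqrHigh` (minutes).
#' @export
weightedQuantileStats <- function(tt, pop, quantileBand = c(0.8, 1),
                                  includeUnreachable = TRUE) {
  .stopIfGridMismatch(tt@grid, pop@grid, "travel time and population")
  if (length(quantileBand) != 2 || any(quantileBand < 0) ||
      any(quantileBand > 1) || quantileBand[1] >= quantileBand[2])
    stop("quantileBand must be an increasing pair within [0, 1]",
         call. = FALSE)
  t <- as.vector(tt@values); w <- as.vector(pop@values)
  keep <- !is.na(t) & !is.na(w) & w > 0
  if (!includeUnreachable) keep <- keep & is.finite(t)
  t <- t[keep]; w <- w[keep]
  if (sum(w) <= 0) stop("total population is zero", call. = FALSE)
  o <- order(t)
  t <- t[o]; w <- w[o]
  W <- sum(w)
  cum <- cumsum(w)
  lo <- quantileBand[1] * W; hi <- quantileBand[2] * W
  wBand <- pmax(0, pmin(cum, hi) - pmax(cum - w, lo))
  q <- weightedQuantile(t, wBand, c(0.25, 0.5, 0.75))
  list(median = q[2], iqrLow = q[1], iqrHigh = q[3])
}

#' CategoricalRaster: travel-time categories over populated areas
#'
#' Integer raster of category indices into `labels`; `NA` where masked.
#'
#' @slot labels category labels, in order.
#' @export
setClass("CategoricalRaster", contains = "GridLayer",
         representation(labels = "character"))

#' Categorise travel time over populated areas
#'
#' Assigns each populated cell (at least `minPop` persons, default one adult
#' aged 60+ per cell) its travel-time category under the scheme; unreachable
#' cells fall in the top open-ended category; cells below the population
#' threshold are masked (`NA`). Categories are closed-left: a travel time
#' exactly on a boundary belongs to the higher category.
#'
#' @param tt a [TravelTimeRaster-class].
#' @param pop a [PopulationRaster-class] on the same grid.
#' @param scheme a [CutoffScheme-class].
#' @param minPop populated-area threshold in persons per cell.
#' @return A [CategoricalRaster-class].
#' @export
categorizeMap <- function(tt, pop, scheme, minPop = 1) {
  .stopIfGridMismatch(tt@grid, pop@grid, "travel time and population")
  validObject(scheme)
  t <- tt@values
  cat <- matrix(NA_integer_, nrow(t), ncol(t))
  live <- !is.na(t) & !is.na(pop@values) & pop@values >= minPop
  cat[live] <- findInterval(t[live], scheme@boundaries) + 1L
  new("CategoricalRaster", grid = tt@grid, values = cat,
      labels = scheme@labels)
}

#' Population-weighted travel-time histogram
#'
#' Bins are closed-left/open-right of width `binWidth` minutes starting at
#' zero; a final open-ended bin collects the unreachable population. With
#' `regions`, cells are attributed to regions by cell-centre
#' point-in-polygon and one histogram is returned per region.
#'
#' @param tt a [TravelTimeRaster-class].
#' @param pop a [PopulationRaster-class] on the same grid.
#' @param binWidth minutes (> 0).
#' @param regions optional named list of polygon matrices.
#' @return data.frame with columns region, bin_low, bin_high (minutes,
#'   `Inf` for the open-ended bin), population.
#' @export
distributionTable <- function(tt, pop, binWidth = 30, regions = NULL) {
  .stopIfGridMismatch(tt@grid, pop@grid, "travel time and population")
  if (binWidth <= 0) stop("binWidth must be > 0", call. = FALSE)
  t <- as.vector(tt@values); w <- as.vector(pop@values)
  keep <- !is.na(t) & !is.na(w)
  idx <- which(keep)
  grid <- tt@grid
  if (is.null(regions)) {
    reg <- rep("all", length(idx))
  } else {
    rc <- arrayInd(idx, dim(tt@values))
    xy <- xyFromCell(grid, rc[, 1], rc[, 2])
    reg <- assignRegions(xy$x, xy$y, regions)
  }
  t <- t[idx]; w <- w[idx]
  maxFin <- if (any(is.finite(t))) max(t[is.finite(t)]) else 0
  nBins <- max(1L, ceiling((maxFin + 1e-9) / binWidth))
  regionNames <- if (is.null(regions)) "all" else names(regions)
  out <- list()
  for (rn in regionNames) {
    sel <- !is.na(reg) & reg == rn
    ## finite t <= maxFin < nBins * binWidth, so the index never overflows
    binIdx <- ifelse(is.finite(t), floor(t / binWidth) + 1L, nBins + 1L)
    popBin <- vapply(seq_len(nBins + 1L), function(b) sum(w[sel & binIdx == b]),
                     numeric(1))
    out[[rn]] <- data.frame(
      region = rn,
      bin_low = c((seq_len(nBins) - 1L) * binWidth, Inf),
      bin_high = c(seq_len(nBins) * binWidth, Inf),
      population = popBin, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Population-weighted accessibility summary
#'
#' Per region: total population, the population share in each travel-time
#' category of the scheme (unreachable population counts in the top
#' open-ended category), the proportion above the headline cut-off with its
#' Wilson score interval, the worst-quintile weighted median and IQR of
#' travel time, and the unreachable share.
#'
#' @param tt a [TravelTimeRaster-class] on the population grid.
#' @param pop a [PopulationRaster-class] on the same grid.
#' @param scheme a [CutoffScheme-class].
#' @param cutoff headline cut-off in minutes.
#' @param wilsonN effective denominator policy: `NULL` (default) uses the
#'   number of populated cells per region, otherwise a fixed number.
#' @param regions optional named list of polygon matrices; default one
#'   region `"all"`.
#' @param z normal quantile for the Wilson interval.
#' @return An [AccessSummary-class].
#' @export
accessSummary <- function(tt, pop, scheme, cutoff, wilsonN = NULL,
                          regions = NULL, z = 1.959964) {
  .stopIfGridMismatch(tt@grid, pop@grid, "travel time and population")
  validObject(scheme)
  t <- as.vector(tt@values); w <- as.vector(pop@values)
  keep <- !is.na(t) & !is.na(w)
  idx <- which(keep)
  if (is.null(regions)) {
    reg <- rep("all", length(idx)); regionNames <- "all"
  } else {
    rc <- arrayInd(idx, dim(tt@values))
    xy <- xyFromCell(tt@grid, rc[, 1], rc[, 2])
    reg <- assignRegions(xy$x, xy$y, regions)
    regionNames <- names(regions)
  }
  t <- t[idx]; w <- w[idx]
  nCat <- length(scheme@labels)
  rows <- list()
  for (rn in regionNames) {
    sel <- !is.na(reg) & reg == rn
    tr <- t[sel]; wr <- w[sel]
    W <- sum(wr)
    if (W <= 0) {
      warning("region '", rn, "' has zero population; skipped",
              call. = FALSE)
      next
    }
    catIdx <- findInterval(tr, scheme@boundaries) + 1L
    shares <- vapply(seq_len(nCat),
                     function(k) sum(wr[catIdx == k]) / W, numeric(1))
    p <- sum(wr[tr > cutoff]) / W
    nEff <- if (is.null(wilsonN)) sum(wr >= 1) else wilsonN
    ci <- wilsonInterval(p, nEff, z)
    q5 <- local({
      o <- order(tr); ts <- tr[o]; ws <- wr[o]
      cum <- cumsum(ws)
      wBand <- pmax(0, pmin(cum, W) - pmax(cum - ws, 0.8 * W))
      qq <- weightedQuantile(ts, wBand, c(0.25, 0.5, 0.75))
      list(median = qq[2], lo = qq[1], hi = qq[3])
    })
    row <- data.frame(region = rn, total_pop = W, stringsAsFactors = FALSE)
    for (k in seq_len(nCat))
      row[[paste0("share_", gsub("[^0-9A-Za-z]+", "_", scheme@labels[k]))]] <-
        shares[k]
    row$p_above_cutoff <- p
    row$ci_low <- ci[1, "low"]; row$ci_high <- ci[1, "high"]
    row$wilson_n <- nEff
    row$q5_median_min <- q5$median
    row$q5_iqr_low <- q5$lo; row$q5_iqr_high <- q5$hi
    row$share_unreachable <- sum(wr[is.infinite(tr)]) / W
    rows[[rn]] <- row
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("AccessSummary", table = tab, scheme = scheme, cutoff = cutoff)
}

#' @rdname accessSummary
#' @param x an [AccessSummary-class].
#' @export
summaryTable <- function(x) x@table

setMethod("show", "AccessSummary", function(object) {
  cat(sprintf("AccessSummary (cut-off %g min, categories %s)\n",
              object@cutoff, paste(object@scheme@labels, collapse = ", ")))
  print(object@table, digits = 4)
})
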