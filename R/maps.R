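#' @include AllClasses.R grid.R stats.R
NULL

.CATEGORY_PALETTE <- c("#1a9641", "#fdae61", "#d7191c", "#7f0000")

#' Render accessibility maps to PNG
#'
#' Writes a two-panel PNG: the categorical travel-time map over populated
#' areas (four-colour palette, legend from the raster's labels) and a
#' population-density panel. Purely presentational; failures are logged as
#' warnings, never fatal.
#'
#' @param categorical a [CategoricalRaster-class] from [categorizeMap()].
#' @param pop a [PopulationRaster-class] on the same grid.
#' @param path output `.png` path.
#' @param width,height device size in pixels.
#' @return `path` invisibly, or `NA` if rendering failed.
#' @export
renderMaps <- function(categorical, pop, path, width = 1200, height = 600) {
  tryCatch({
    v <- categorical@values
    if (all(is.na(v)))
      warning("categorical raster is fully masked; writing a blank map",
              call. = FALSE)
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(1, 2), mar = c(2, 2, 3, 6))
    nCat <- length(categorical@labels)
    ## image() draws column-major from bottom; flip rows for map orientation
    flip <- function(m) t(m[nrow(m):1, , drop = FALSE])
    graphics::image(flip(v), zlim = c(1, nCat),
                    col = .CATEGORY_PALETTE[seq_len(nCat)], axes = FALSE,
                    main = "Travel time category (populated areas)")
    graphics::legend("topright", inset = c(-0.12, 0), xpd = TRUE,
                     legend = categorical@labels,
                     fill = .CATEGORY_PALETTE[seq_len(nCat)], bty = "n")
    p <- pop@values
    graphics::image(flip(log1p(p)), col = grDevices::hcl.colors(64, "Blues",
                                                                rev = TRUE),
                    axes = FALSE, main = "Population density (log scale)")
    invisible(path)
  }, error = function(e) {
    warning("map rendering failed: ", conditionMessage(e), call. = FALSE)
    invisible(NA_character_)
  })
}
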