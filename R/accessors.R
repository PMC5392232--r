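#' Accessors for rangeOverlap classes
#'
#' Small generic accessors for the package's S4 containers: the pack label,
#' the fix table, fix counts, grid geometry, bandwidths, isopleth levels and
#' areas.
#'
#' @param object a [FixSeries-class], [UtilizationDistribution-class],
#'   [IsoplethSet-class] or [PackScenario-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("packId", function(object) standardGeneric("packId"))

#' @rdname accessors
#' @export
setMethod("packId", "FixSeries", function(object) object@packId)
#' @rdname accessors
#' @export
setMethod("packId", "UtilizationDistribution", function(object) object@packId)
#' @rdname accessors
#' @export
setMethod("packId", "IsoplethSet", function(object) object@packId)
#' @rdname accessors
#' @export
setMethod("packId", "PackScenario", function(object) object@packId)

#' @rdname accessors
#' @export
setGeneric("fixTable", function(object) standardGeneric("fixTable"))
#' @rdname accessors
#' @export
setMethod("fixTable", "FixSeries", function(object) object@fixes)

#' @rdname accessors
#' @export
setGeneric("nFixes", function(object) standardGeneric("nFixes"))
#' @rdname accessors
#' @export
setMethod("nFixes", "FixSeries", function(object) nrow(object@fixes))
#' @rdname accessors
#' @export
setMethod("nFixes", "UtilizationDistribution", function(object) object@nFixes)

#' @rdname accessors
#' @export
setGeneric("analysisWindow", function(object) standardGeneric("analysisWindow"))
#' @rdname accessors
#' @export
setMethod("analysisWindow", "FixSeries", function(object) object@window)

#' @rdname accessors
#' @export
setGeneric("cellSize", function(object) standardGeneric("cellSize"))
#' @rdname accessors
#' @export
setMethod("cellSize", "UtilizationDistribution", function(object) object@cellSize)
#' @rdname accessors
#' @export
setMethod("cellSize", "IsoplethSet", function(object) object@cellSize)

#' @rdname accessors
#' @export
setGeneric("udDensity", function(object) standardGeneric("udDensity"))
#' @rdname accessors
#' @export
setMethod("udDensity", "UtilizationDistribution", function(object) object@density)

#' @rdname accessors
#' @export
setGeneric("bandwidth", function(object) standardGeneric("bandwidth"))
#' @rdname accessors
#' @export
setMethod("bandwidth", "UtilizationDistribution", function(object) object@bandwidth)

#' @rdname accessors
#' @export
setGeneric("isoLevels", function(object) standardGeneric("isoLevels"))
#' @rdname accessors
#' @export
setMethod("isoLevels", "IsoplethSet", function(object) object@levels)

#' @rdname accessors
#' @param level one of the stored isopleth levels.
#' @export
setGeneric("isoArea", function(object, level) standardGeneric("isoArea"))
#' @rdname accessors
#' @export
setMethod("isoArea", "IsoplethSet", function(object, level) {
  i <- match(level, object@levels)
  if (is.na(i)) stop("no isopleth at level ", level)
  object@areaKm2[i]
})

#' @rdname accessors
#' @export
setGeneric("isoMask", function(object, level) standardGeneric("isoMask"))
#' @rdname accessors
#' @export
setMethod("isoMask", "IsoplethSet", function(object, level) {
  i <- match(level, object@levels)
  if (is.na(i)) stop("no isopleth at level ", level)
  object@masks[[i]]
})

#' @rdname accessors
#' @export
setGeneric("packSize", function(object) standardGeneric("packSize"))
#' @rdname accessors
#' @export
setMethod("packSize", "PackScenario",
          function(object) object@nAdults + object@nYearlings + object@nPups)

setMethod("show", "FixSeries", function(object) {
  cat("FixSeries for pack '", object@packId, "'\n", sep = "")
  cat("  ", nrow(object@fixes), " fixes, ",
      format(object@window[1], "%Y-%m-%d"), " to ",
      format(object@window[2], "%Y-%m-%d"), " (UTC)\n", sep = "")
  if (nrow(object@fixes)) {
    cat(sprintf("  x: [%.0f, %.0f] m; y: [%.0f, %.0f] m\n",
                min(object@fixes$x), max(object@fixes$x),
                min(object@fixes$y), max(object@fixes$y)))
  }
})

setMethod("show", "UtilizationDistribution", function(object) {
  d <- dim(object@density)
  cat("UtilizationDistribution for pack '", object@packId, "'\n", sep = "")
  cat(sprintf("  grid %d x %d cells of %.1f m; bandwidth (%.1f, %.1f) m; n = %d fixes\n",
              d[1], d[2], object@cellSize, object@bandwidth[1],
              object@bandwidth[2], object@nFixes))
})

setMethod("show", "IsoplethSet", function(object) {
  cat("IsoplethSet for pack '", object@packId, "'\n", sep = "")
  for (i in seq_along(object@levels))
    cat(sprintf("  %2.0f%% isopleth: %.2f km2\n",
                100 * object@levels[i], object@areaKm2[i]))
})

setMethod("show", "PackScenario", function(object) {
  cat(sprintf("PackScenario '%s': centre (%.1f, %.1f) km, sigma %.2f km, tau %.0f h, %d dogs\n",
              object@packId, object@center[1], object@center[2],
              object@sigma, object@tau, packSize(object)))
})

setMethod("show", "DyadScenario", function(object) {
  cat(sprintf("DyadScenario %s - %s (%s%s)\n", object@packA@packId,
              object@packB@packId, object@relatedness,
              if (is.na(object@relationshipType)) ""
              else paste0(", ", object@relationshipType)))
})
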