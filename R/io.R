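# Plain-text interchange: CSV ingest (with optional lon/lat projection),
# ESRI ASCII rasters for UDs, and GeoJSON FeatureCollections for isopleth
# and overlap-zone polygons. No binary formats anywhere.

# Local equirectangular projection about the centroid: adequate at study
# scale (< 100 km) where distortion is negligible.
.projectLonLat <- function(lon, lat) {
  R <- 6371000
  lat0 <- mean(lat) * pi / 180
  lon0 <- mean(lon) * pi / 180
  list(x = R * cos(lat0) * (lon * pi / 180 - lon0),
       y = R * (lat * pi / 180 - mean(lat) * pi / 180))
}

#' Read a GPS fix table
#'
#' Expects columns `pack_id`, `timestamp` (ISO-8601, UTC) and either
#' planar `x_m`, `y_m` in metres or `lon`, `lat` in degrees; lon/lat are
#' projected to local planar metres (equirectangular about the centroid).
#'
#' @param path CSV file path.
#' @return data.frame with `pack_id`, `timestamp`, `x_m`, `y_m`.
#' @export
readFixesCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"pack_id" %in% names(d) || !"timestamp" %in% names(d))
    stop("fixes CSV needs pack_id and timestamp columns")
  if (all(c("x_m", "y_m") %in% names(d))) {
    d[, c("pack_id", "timestamp", "x_m", "y_m")]
  } else if (all(c("lon", "lat") %in% names(d))) {
    p <- .projectLonLat(d$lon, d$lat)
    data.frame(pack_id = d$pack_id, timestamp = d$timestamp,
               x_m = p$x, y_m = p$y)
  } else stop("fixes CSV needs x_m/y_m (metres) or lon/lat (degrees)")
}

#' @rdname readFixesCsv
#' @export
readPacksCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pack_id", "n_adults", "n_yearlings", "n_pups")
  if (!all(need %in% names(d)))
    stop("packs CSV needs columns ", paste(need, collapse = ", "))
  d
}

#' @rdname readFixesCsv
#' @export
readDyadsCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("focal_pack", "neighbour_pack", "relatedness")
  if (!all(need %in% names(d)))
    stop("dyads CSV needs columns ", paste(need, collapse = ", "))
  if (!all(d$relatedness %in% c("related", "unrelated")))
    stop("relatedness must be 'related' or 'unrelated'")
  d
}

#' Write a UD as an ESRI ASCII grid
#'
#' Plain-text raster dialect with the standard
#' ncols/nrows/xllcorner/yllcorner/cellsize/NODATA header. Rows are written
#' north to south as the format requires.
#'
#' @param ud a [UtilizationDistribution-class].
#' @param path output file.
#' @export
writeEsriAscii <- function(ud, path) {
  stopifnot(is(ud, "UtilizationDistribution"))
  d <- ud@density
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nrow(d)),
    paste("nrows", ncol(d)),
    paste("xllcorner", format(ud@origin[1], scientific = FALSE)),
    paste("yllcorner", format(ud@origin[2], scientific = FALSE)),
    paste("cellsize", format(ud@cellSize, scientific = FALSE)),
    "NODATA_value -9999"), con)
  for (j in rev(seq_len(ncol(d))))
    writeLines(paste(format(d[, j], digits = 8), collapse = " "), con)
  invisible(path)
}

.ringToCoords <- function(df) {
  xy <- cbind(df$x, df$y)
  if (nrow(xy) < 3L) return(NULL)
  if (any(xy[1, ] != xy[nrow(xy), ])) xy <- rbind(xy, xy[1, ])
  lapply(seq_len(nrow(xy)), function(i) c(xy[i, 1], xy[i, 2]))
}

#' Write isopleth boundary polygons as GeoJSON
#'
#' One FeatureCollection per pack; each feature is a Polygon ring of one
#' isopleth boundary with properties `pack_id` and `level`. Coordinates
#' are the planar analysis metres (not geographic); the export is for
#' inspection and display only — all areas and intersections in the
#' analysis are raster-based.
#'
#' @param iso an [IsoplethSet-class].
#' @param path output file.
#' @export
writeIsoplethGeoJSON <- function(iso, path) {
  stopifnot(is(iso, "IsoplethSet"))
  features <- list()
  for (i in seq_along(iso@levels)) {
    for (ring in iso@polygons[[i]]) {
      coords <- .ringToCoords(ring)
      if (is.null(coords)) next
      features[[length(features) + 1L]] <- list(
        type = "Feature",
        properties = list(pack_id = iso@packId, level = iso@levels[i]),
        geometry = list(type = "Polygon", coordinates = list(coords)))
    }
  }
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a dyad's overlap-zone mask as GeoJSON
#'
#' Traces the 0/1 shared-grid mask from [overlapZoneMask()] with marching
#' squares and writes the rings as Polygon features (properties
#' `focal_pack`, `neighbour_pack`, `level`).
#'
#' @param zone result of [overlapZoneMask()].
#' @param focal,neighbour pack labels for the feature properties.
#' @param level isopleth level recorded in the properties.
#' @param path output file.
#' @export
writeZoneGeoJSON <- function(zone, focal, neighbour, level, path) {
  m <- zone$mask
  features <- list()
  if (any(m)) {
    xc <- zone$origin[1] + (seq_len(nrow(m)) - 0.5) * zone$cell
    yc <- zone$origin[2] + (seq_len(ncol(m)) - 0.5) * zone$cell
    cls <- grDevices::contourLines(xc, yc, m + 0, levels = 0.5)
    for (cl in cls) {
      coords <- .ringToCoords(data.frame(x = cl$x, y = cl$y))
      if (is.null(coords)) next
      features[[length(features) + 1L]] <- list(
        type = "Feature",
        properties = list(focal_pack = focal, neighbour_pack = neighbour,
                          level = level),
        geometry = list(type = "Polygon", coordinates = list(coords)))
    }
  }
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Small deterministic content hash (FNV-style) for run manifests.
.configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- (h * 16777619 + b) %% 4294967291
  sprintf("%010.0f", h)
}
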