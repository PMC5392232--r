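# Fixed-kernel utilisation distributions and isopleth extraction.
#
# The protocol mirrors classic telemetry practice: thin raw fixes to two per
# day (an early-morning fix plus one 12 h later), drop denning windows,
# smooth with a bivariate Gaussian product kernel at the reference
# bandwidth h_i = s_i * n^(-1/6) per axis, and cut probability-mass
# isopleths on the raster.

#' Thin raw fixes to the two-per-day protocol
#'
#' Retains at most two fixes per calendar day (UTC): the earliest fix within
#' +/- `toleranceMin` minutes of one of the candidate morning clock times,
#' and the fix nearest 12 h after it (again within the tolerance). Days
#' missing one slot contribute the other; days missing both contribute
#' nothing. When no morning fix exists the evening slot is searched relative
#' to the candidate times directly.
#'
#' @param fixes data.frame with columns `timestamp`, `x`, `y`, or a
#'   [FixSeries-class].
#' @param packId pack label for the result (taken from the input when it is
#'   a `FixSeries`).
#' @param morningCandidates decimal clock hours of permissible first fixes.
#' @param intervalHours nominal gap to the second daily fix.
#' @param toleranceMin slot matching tolerance in minutes.
#' @return a [FixSeries-class] with at most two fixes per day.
#' @export
subsampleTwoDaily <- function(fixes, packId = "pack",
                              morningCandidates = c(5, 6, 6.5),
                              intervalHours = 12, toleranceMin = 30) {
  if (is(fixes, "FixSeries")) {
    packId <- packId(fixes)
    fixes <- fixTable(fixes)
  }
  if (!is.data.frame(fixes) || nrow(fixes) == 0L)
    stop("empty fix input")
  if (length(morningCandidates) == 0L)
    stop("morningCandidates must be non-empty")
  fs <- fixSeries(packId, fixes)          # parses/validates timestamps
  f <- fixTable(fs)
  tol <- toleranceMin * 60
  day <- as.Date(f$timestamp, tz = "UTC")
  tnum <- as.numeric(f$timestamp)
  keep <- logical(nrow(f))
  for (d in unique(day)) {
    idx <- which(day == d)
    day0 <- as.numeric(as.POSIXct(paste(as.Date(d), "00:00:00"), tz = "UTC"))
    slots <- day0 + sort(morningCandidates) * 3600
    # morning: earliest fix within tolerance of any candidate slot
    nearAny <- idx[vapply(idx, function(i)
      any(abs(tnum[i] - slots) <= tol), logical(1))]
    morning <- if (length(nearAny)) nearAny[which.min(tnum[nearAny])] else NA
    if (!is.na(morning)) {
      keep[morning] <- TRUE
      target <- tnum[morning] + intervalHours * 3600
    } else {
      target <- slots[1] + intervalHours * 3600
    }
    rest <- setdiff(idx, morning)
    if (length(rest)) {
      dd <- abs(tnum[rest] - target)
      if (is.na(morning)) {
        # try each candidate-based evening slot in clock order
        for (s in slots + intervalHours * 3600) {
          dd <- abs(tnum[rest] - s)
          if (min(dd) <= tol) break
        }
      }
      if (min(dd) <= tol) keep[rest[which.min(dd)]] <- TRUE
    }
  }
  if (!any(keep)) stop("no fixes matched the two-per-day schedule")
  fixSeries(packId, f[keep, , drop = FALSE], window = analysisWindow(fs))
}

#' Remove fixes inside a date interval
#'
#' Drops all fixes whose timestamps fall inside the closed interval
#' `[start, end]` — typically an annual denning period, excluded because
#' ranges contract around the den and would bias the kernel estimate.
#'
#' @param series a [FixSeries-class].
#' @param start,end interval bounds (Date or POSIXct; dates span the whole
#'   day).
#' @return the filtered [FixSeries-class]; order preserved.
#' @export
excludeWindow <- function(series, start, end) {
  stopifnot(is(series, "FixSeries"))
  toNum <- function(z, endOfDay = FALSE) {
    if (inherits(z, "Date"))
      z <- as.POSIXct(paste(z, if (endOfDay) "23:59:59" else "00:00:00"),
                      tz = "UTC")
    as.numeric(as.POSIXct(z, tz = "UTC"))
  }
  s <- toNum(start); e <- toNum(end, endOfDay = TRUE)
  if (e < s) stop("exclusion interval is ill-formed (end before start)")
  tt <- as.numeric(fixTable(series)$timestamp)
  keep <- tt < s | tt > e
  if (!any(keep))
    stop("exclusion interval removes every fix of pack '",
         packId(series), "'")
  fixSeries(packId(series), fixTable(series)[keep, , drop = FALSE],
            window = analysisWindow(series))
}

#' Reference bandwidth (hRef)
#'
#' Per-axis plug-in smoothing parameter: the sample standard deviation of
#' the rescaled coordinates divided by the sixth root of the number of
#' locations, `h_i = s_i * n^(-1/6)`. Equivalent to rescaling each axis to
#' unit SD, smoothing with `n^(-1/6)`, and mapping back.
#'
#' @param series a [FixSeries-class] with at least 5 fixes.
#' @return named numeric `(h_x, h_y)` in metres.
#' @examples
#' \dontrun{referenceBandwidth(track)}
#' @export
referenceBandwidth <- function(series) {
  stopifnot(is(series, "FixSeries"))
  f <- fixTable(series)
  n <- nrow(f)
  if (n < 5L) stop("need at least 5 fixes to compute hRef (got ", n, ")")
  s <- c(stats::sd(f$x), stats::sd(f$y))
  if (any(s == 0)) stop("zero coordinate variance on an axis; hRef undefined")
  h <- s * n^(-1/6)
  names(h) <- c("h_x", "h_y")
  h
}

#' Estimate a gridded utilisation distribution
#'
#' Fixed-bandwidth bivariate Gaussian product-kernel density on a regular
#' raster. The grid is the fix bounding box expanded by
#' `marginFactor * max(h)` on every side; cell densities are renormalised to
#' integrate to exactly 1 so mass-based isopleths are well defined.
#'
#' @param series a [FixSeries-class].
#' @param cellSizeM cell edge in metres; by default chosen so the shorter
#'   fix-cloud axis spans at least 100 cells, capped at 512 cells per axis.
#' @param marginFactor grid margin in multiples of the larger bandwidth.
#' @param bandwidth optional `(h_x, h_y)` override in metres; defaults to
#'   [referenceBandwidth()].
#' @param maxCellsPerAxis hard cap; a user-chosen `cellSizeM` breaching it
#'   is an error suggesting a coarser cell.
#' @return a [UtilizationDistribution-class].
#' @export
estimateUD <- function(series, cellSizeM = NULL, marginFactor = 3,
                       bandwidth = NULL, maxCellsPerAxis = 512L) {
  stopifnot(is(series, "FixSeries"))
  f <- fixTable(series)
  h <- if (is.null(bandwidth)) referenceBandwidth(series)
       else { stopifnot(length(bandwidth) == 2L, all(bandwidth > 0))
              as.numeric(bandwidth) }
  margin <- marginFactor * max(h)
  xr <- range(f$x); yr <- range(f$y)
  spans <- c(diff(xr), diff(yr))
  userCell <- !is.null(cellSizeM)
  if (!userCell) {
    base <- min(spans[spans > 0], 2 * margin)
    cellSizeM <- base / 100
    fullSpan <- max(spans) + 2 * margin
    if (fullSpan / cellSizeM > maxCellsPerAxis - 1L)
      cellSizeM <- fullSpan / (maxCellsPerAxis - 1L)
  }
  if (cellSizeM <= 0) stop("cellSizeM must be positive")
  origin <- c(xr[1] - margin, yr[1] - margin)
  nx <- ceiling((xr[2] + margin - origin[1]) / cellSizeM)
  ny <- ceiling((yr[2] + margin - origin[2]) / cellSizeM)
  if (nx > maxCellsPerAxis || ny > maxCellsPerAxis)
    stop(sprintf(paste0("grid would be %d x %d cells (cap %d per axis); ",
                        "use a larger cellSizeM"), nx, ny, maxCellsPerAxis))
  xc <- origin[1] + (seq_len(nx) - 0.5) * cellSizeM
  yc <- origin[2] + (seq_len(ny) - 0.5) * cellSizeM
  # separable kernel: density = Fx %*% t(Fy) / n
  Fx <- outer(xc, f$x, function(g, v) stats::dnorm(g, v, h[1]))
  Fy <- outer(yc, f$y, function(g, v) stats::dnorm(g, v, h[2]))
  dens <- (Fx %*% t(Fy)) / nrow(f)
  dens <- dens / (sum(dens) * cellSizeM^2)
  new("UtilizationDistribution", packId = packId(series),
      origin = origin, cellSize = cellSizeM, density = dens,
      bandwidth = unname(h), nFixes = nrow(f))
}

#' Extract probability-mass isopleths from a UD
#'
#' For each level p the isopleth mask is the smallest set of grid cells,
#' filled in decreasing density order, whose cumulative probability mass
#' reaches p. Cells of equal density are admitted in ascending row-major
#' index order, making the cut deterministic. Masks are nested across
#' levels by construction; areas follow the raster convention (cell count
#' times cell area). Display polygons are traced by marching squares at the
#' per-level density threshold.
#'
#' @param ud a [UtilizationDistribution-class].
#' @param levels strictly increasing probabilities in (0, 1).
#' @return an [IsoplethSet-class].
#' @export
extractIsopleths <- function(ud, levels = c(0.5, 0.75, 0.95)) {
  stopifnot(is(ud, "UtilizationDistribution"))
  levels <- as.numeric(levels)
  if (any(levels <= 0) || any(levels >= 1) || any(diff(levels) <= 0))
    stop("levels must be strictly increasing probabilities in (0, 1)")
  d <- ud@density
  cellArea <- ud@cellSize^2
  ord <- order(-as.vector(d), seq_along(d))   # density desc, index asc
  cmass <- cumsum(as.vector(d)[ord]) * cellArea
  total <- cmass[length(cmass)]
  masks <- vector("list", length(levels))
  thresholds <- numeric(length(levels))
  areas <- numeric(length(levels))
  polys <- vector("list", length(levels))
  xc <- ud@origin[1] + (seq_len(nrow(d)) - 0.5) * ud@cellSize
  yc <- ud@origin[2] + (seq_len(ncol(d)) - 0.5) * ud@cellSize
  for (i in seq_along(levels)) {
    if (levels[i] >= total + 1e-12)
      stop(sprintf("level %.3f exceeds the grid-representable mass %.6f",
                   levels[i], total))
    m <- which(cmass >= levels[i] - 1e-12)[1]
    mask <- matrix(FALSE, nrow(d), ncol(d))
    mask[ord[seq_len(m)]] <- TRUE
    masks[[i]] <- mask
    thresholds[i] <- as.vector(d)[ord[m]]
    areas[i] <- m * cellArea / 1e6
    polys[[i]] <- lapply(
      suppressWarnings(grDevices::contourLines(xc, yc, d,
                                               levels = thresholds[i])),
      function(cl) data.frame(x = cl$x, y = cl$y))
  }
  new("IsoplethSet", packId = ud@packId, levels = levels, masks = masks,
      areaKm2 = areas, thresholds = thresholds, origin = ud@origin,
      cellSize = ud@cellSize, polygons = polys)
}

# Logical vector: is each point (x, y) inside `mask` on the grid given by
# origin/cellSize? Half-open cell membership [x0, x0 + cell) per axis.
.pointsInMask <- function(x, y, mask, origin, cellSize) {
  ix <- floor((x - origin[1]) / cellSize) + 1L
  iy <- floor((y - origin[2]) / cellSize) + 1L
  ok <- ix >= 1L & ix <= nrow(mask) & iy >= 1L & iy <= ncol(mask)
  res <- logical(length(x))
  res[ok] <- mask[cbind(ix[ok], iy[ok])]
  res
}

#' Fraction of a fix series inside an isopleth
#'
#' @param series a [FixSeries-class].
#' @param iso an [IsoplethSet-class] (typically the same pack's).
#' @param level one of the stored isopleth levels.
#' @return proportion of fixes inside the mask, in [0, 1].
#' @export
fixFractionInIsopleth <- function(series, iso, level) {
  stopifnot(is(series, "FixSeries"), is(iso, "IsoplethSet"))
  f <- fixTable(series)
  if (nrow(f) == 0L) stop("empty fix series")
  mean(.pointsInMask(f$x, f$y, isoMask(iso, level), iso@origin, iso@cellSize))
}
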