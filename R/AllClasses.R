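#' @import methods
NULL

setOldClass("POSIXct")

#' One group's time-ordered GPS fixes over an analysis window
#'
#' A `FixSeries` holds the telemetry fixes of a single pack: a strictly
#' time-ordered table of timestamps (UTC) and planar coordinates in metres,
#' together with the analysis window the fixes belong to.
#'
#' @slot packId single pack label.
#' @slot fixes data.frame with columns `timestamp` (POSIXct, UTC), `x`, `y`
#'   (metres, finite).
#' @slot window POSIXct vector of length 2, the analysis window; all fixes
#'   fall inside it.
#'
#' @seealso [fixSeries()], [subsampleTwoDaily()], [estimateUD()]
#' @export
setClass("FixSeries",
  slots = c(packId = "character", fixes = "data.frame", window = "POSIXct"))

setValidity("FixSeries", function(object) {
  msg <- character()
  if (length(object@packId) != 1L || is.na(object@packId))
    msg <- c(msg, "packId must be a single non-NA label")
  f <- object@fixes
  if (!all(c("timestamp", "x", "y") %in% names(f)))
    msg <- c(msg, "fixes must have columns timestamp, x, y")
  else {
    if (!inherits(f$timestamp, "POSIXct"))
      msg <- c(msg, "fixes$timestamp must be POSIXct")
    if (nrow(f) > 1L && any(diff(as.numeric(f$timestamp)) <= 0))
      msg <- c(msg, "timestamps must be strictly increasing")
    if (!all(is.finite(f$x)) || !all(is.finite(f$y)))
      msg <- c(msg, "coordinates must be finite")
    if (length(object@window) == 2L && nrow(f) > 0L) {
      w <- as.numeric(object@window)
      tt <- as.numeric(f$timestamp)
      if (min(tt) < w[1] || max(tt) > w[2])
        msg <- c(msg, "all fixes must lie inside the analysis window")
    }
  }
  if (length(object@window) != 2L)
    msg <- c(msg, "window must have length 2")
  if (length(msg)) msg else TRUE
})

#' Construct a FixSeries
#'
#' @param packId single pack label.
#' @param fixes data.frame with columns `timestamp` (POSIXct or ISO-8601
#'   character, interpreted as UTC), `x`, `y` in metres.
#' @param window optional POSIXct length-2 analysis window; defaults to the
#'   day-aligned span of the fixes.
#' @return a [FixSeries-class] object.
#' @export
fixSeries <- function(packId, fixes, window = NULL) {
  if (!is.data.frame(fixes) || nrow(fixes) == 0L)
    stop("'fixes' must be a non-empty data.frame")
  fixes <- as.data.frame(fixes)[, c("timestamp", "x", "y")]
  if (is.character(fixes$timestamp)) {
    ts <- as.POSIXct(strptime(fixes$timestamp, "%Y-%m-%dT%H:%M:%S",
                              tz = "UTC"))
    bad <- is.na(ts)
    ts[bad] <- as.POSIXct(strptime(fixes$timestamp[bad],
                                   "%Y-%m-%d %H:%M:%S", tz = "UTC"))
    if (anyNA(ts))
      stop("unparseable timestamps at rows: ",
           paste(utils::head(which(is.na(ts)), 5L), collapse = ", "))
    fixes$timestamp <- ts
  }
  attr(fixes$timestamp, "tzone") <- "UTC"
  fixes <- fixes[order(fixes$timestamp), , drop = FALSE]
  rownames(fixes) <- NULL
  if (is.null(window)) {
    rng <- range(fixes$timestamp)
    window <- c(trunc(rng[1], "days"), trunc(rng[2], "days") + 86400)
  }
  window <- as.POSIXct(window, tz = "UTC")
  new("FixSeries", packId = as.character(packId), fixes = fixes, window = window)
}

#' Gridded utilisation distribution (UD)
#'
#' A kernel-density surface on a regular raster, normalised so the cell
#' densities integrate to unit probability mass. Rows of `density` index x,
#' columns index y; the centre of cell (i, j) is at
#' `origin + (c(i, j) - 0.5) * cellSize`.
#'
#' @slot packId pack label.
#' @slot origin lower-left corner (metres) of the grid.
#' @slot cellSize cell edge length in metres.
#' @slot density nx-by-ny non-negative matrix; `sum(density) * cellSize^2 == 1`.
#' @slot bandwidth per-axis kernel bandwidths `(h_x, h_y)` in metres.
#' @slot nFixes number of fixes the surface was estimated from.
#' @seealso [estimateUD()], [extractIsopleths()]
#' @export
setClass("UtilizationDistribution",
  slots = c(packId = "character", origin = "numeric", cellSize = "numeric",
            density = "matrix", bandwidth = "numeric", nFixes = "integer"))

setValidity("UtilizationDistribution", function(object) {
  msg <- character()
  if (length(object@origin) != 2L) msg <- c(msg, "origin must have length 2")
  if (length(object@cellSize) != 1L || object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a positive scalar")
  if (any(object@density < 0)) msg <- c(msg, "density must be non-negative")
  mass <- sum(object@density) * object@cellSize^2
  if (abs(mass - 1) > 1e-6)
    msg <- c(msg, sprintf("density mass is %.8f, must be 1 within 1e-6", mass))
  if (length(object@bandwidth) != 2L || any(object@bandwidth <= 0))
    msg <- c(msg, "bandwidth must be two positive values")
  if (length(msg)) msg else TRUE
})

#' Isopleth (utilisation contour) set of a UD
#'
#' The probability-mass regions of a [UtilizationDistribution-class]: for
#' each level p, the smallest set of grid cells (highest density first)
#' whose mass reaches p. Masks are nested across levels and areas follow the
#' raster convention (cell count times cell area).
#'
#' @slot packId pack label.
#' @slot levels increasing probabilities, typically 0.50, 0.75, 0.95.
#' @slot masks list of logical nx-by-ny matrices, one per level.
#' @slot areaKm2 per-level region area in square kilometres.
#' @slot thresholds per-level density cut value.
#' @slot origin,cellSize grid geometry inherited from the UD (metres).
#' @slot polygons per-level list of boundary rings (display only), each a
#'   data.frame of x, y vertices from marching-squares contouring.
#' @seealso [extractIsopleths()], [directionalOverlap()]
#' @export
setClass("IsoplethSet",
  slots = c(packId = "character", levels = "numeric", masks = "list",
            areaKm2 = "numeric", thresholds = "numeric", origin = "numeric",
            cellSize = "numeric", polygons = "list"))

setValidity("IsoplethSet", function(object) {
  msg <- character()
  k <- length(object@levels)
  if (length(object@masks) != k || length(object@areaKm2) != k)
    msg <- c(msg, "levels, masks and areaKm2 must have equal length")
  if (k > 1L && any(diff(object@levels) <= 0))
    msg <- c(msg, "levels must be strictly increasing")
  if (k >= 1L) {
    for (i in seq_len(k - 1L)) {
      if (any(object@masks[[i]] & !object@masks[[i + 1L]])) {
        msg <- c(msg, "masks must be nested across increasing levels")
        break
      }
    }
    ca <- object@cellSize^2 / 1e6
    cnt <- vapply(object@masks, sum, numeric(1))
    if (any(abs(cnt * ca - object@areaKm2) > 1e-8))
      msg <- c(msg, "areaKm2 must equal cell count times cell area")
  }
  if (length(msg)) msg else TRUE
})

#' Stationary movement scenario for one pack
#'
#' Parameters of the Ornstein-Uhlenbeck (OU) movement process used to
#' emulate territorial residency: an attraction centre, the stationary
#' per-axis positional SD `sigma`, and the relaxation time `tau` governing
#' autocorrelation. Pack composition follows the field convention of adults
#' (over 24 months), yearlings (12-24 months) and pups (under 12 months).
#'
#' @slot packId pack label.
#' @slot center attraction centre (km, planar).
#' @slot sigma stationary SD of position per axis (km), positive.
#' @slot tau OU relaxation time (hours), positive.
#' @slot nAdults,nYearlings,nPups pack composition; a pack needs at least
#'   two individuals (an adult male plus an unrelated adult female).
#' @slot site study-site label.
#' @export
setClass("PackScenario",
  slots = c(packId = "character", center = "numeric", sigma = "numeric",
            tau = "numeric", nAdults = "integer", nYearlings = "integer",
            nPups = "integer", site = "character"))

setValidity("PackScenario", function(object) {
  msg <- character()
  if (!is.finite(object@sigma) || object@sigma <= 0)
    msg <- c(msg, "sigma must be finite and positive")
  if (!is.finite(object@tau) || object@tau <= 0)
    msg <- c(msg, "tau must be finite and positive")
  if (length(object@center) != 2L || !all(is.finite(object@center)))
    msg <- c(msg, "center must be two finite coordinates (km)")
  if (object@nAdults + object@nYearlings + object@nPups < 2L)
    msg <- c(msg, "pack size must be at least 2")
  if (object@nAdults < 0L || object@nYearlings < 0L || object@nPups < 0L)
    msg <- c(msg, "pack composition counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname PackScenario-class
#' @param packId,center,sigma,tau,nAdults,nYearlings,nPups,site see slots.
#' @return a `PackScenario`.
#' @export
packScenario <- function(packId, center, sigma, tau = 24,
                         nAdults = 2L, nYearlings = 0L, nPups = 0L,
                         site = "synthetic") {
  new("PackScenario", packId = as.character(packId),
      center = as.numeric(center), sigma = as.numeric(sigma),
      tau = as.numeric(tau), nAdults = as.integer(nAdults),
      nYearlings = as.integer(nYearlings), nPups = as.integer(nPups),
      site = as.character(site))
}

#' A neighbouring pack pair with a relatedness label
#'
#' @slot packA,packB the two [PackScenario-class] members.
#' @slot relatedness `"related"` or `"unrelated"`.
#' @slot relationshipType for related dyads only, `"female-female"` or
#'   `"male-female"` (which dominant individuals carry the kinship);
#'   `NA` for unrelated dyads.
#' @export
setClass("DyadScenario",
  slots = c(packA = "PackScenario", packB = "PackScenario",
            relatedness = "character", relationshipType = "character"))

setValidity("DyadScenario", function(object) {
  msg <- character()
  if (!object@relatedness %in% c("related", "unrelated"))
    msg <- c(msg, "relatedness must be 'related' or 'unrelated'")
  rel <- identical(object@relatedness, "related")
  hasType <- !is.na(object@relationshipType)
  if (rel && !hasType)
    msg <- c(msg, "related dyads require a relationshipType")
  if (!rel && hasType)
    msg <- c(msg, "unrelated dyads must not carry a relationshipType")
  if (hasType && !object@relationshipType %in% c("female-female", "male-female"))
    msg <- c(msg, "relationshipType must be 'female-female' or 'male-female'")
  if (identical(object@packA@packId, object@packB@packId))
    msg <- c(msg, "a dyad needs two distinct packs")
  if (length(msg)) msg else TRUE
})

#' @rdname DyadScenario-class
#' @param packA,packB,relatedness,relationshipType see slots.
#' @return a `DyadScenario`.
#' @export
dyadScenario <- function(packA, packB, relatedness,
                         relationshipType = NA_character_) {
  new("DyadScenario", packA = packA, packB = packB,
      relatedness = as.character(relatedness),
      relationshipType = as.character(relationshipType))
}

#' Twice-daily GPS fix schedule
#'
#' Telemetry protocol: one fix in the early morning (05:00, 06:00 or 06:30
#' UTC-mapped clock time) and a second 12 h later, every day of the window,
#' with independent Bernoulli dropout of scheduled fixes.
#'
#' @slot windowStart,windowEnd first and last scheduled day (Date).
#' @slot morningHour decimal clock hour of the morning fix, one of 5, 6, 6.5.
#' @slot intervalHours gap to the second daily fix (12).
#' @slot missingness probability in [0, 1) that a scheduled fix is absent.
#' @export
setClass("FixSchedule",
  slots = c(windowStart = "Date", windowEnd = "Date", morningHour = "numeric",
            intervalHours = "numeric", missingness = "numeric"))

setValidity("FixSchedule", function(object) {
  msg <- character()
  if (object@windowEnd < object@windowStart)
    msg <- c(msg, "windowEnd must not precede windowStart")
  ndays <- as.numeric(object@windowEnd - object@windowStart) + 1
  if (ndays > 124)
    msg <- c(msg, "analysis window must not exceed four months (124 days)")
  if (!object@morningHour %in% c(5, 6, 6.5))
    msg <- c(msg, "morningHour must be one of 5, 6, 6.5")
  if (!is.finite(object@missingness) ||
      object@missingness < 0 || object@missingness >= 1)
    msg <- c(msg, "missingness must be in [0, 1)")
  if (!is.finite(object@intervalHours) || object@intervalHours <= 0)
    msg <- c(msg, "intervalHours must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname FixSchedule-class
#' @param windowStart,windowEnd,morningHour,intervalHours,missingness see slots.
#' @return a `FixSchedule`.
#' @export
fixSchedule <- function(windowStart = as.Date("2023-10-01"),
                        windowEnd = as.Date("2024-01-30"),
                        morningHour = 6, intervalHours = 12,
                        missingness = 0.113) {
  new("FixSchedule", windowStart = as.Date(windowStart),
      windowEnd = as.Date(windowEnd), morningHour = as.numeric(morningHour),
      intervalHours = as.numeric(intervalHours),
      missingness = as.numeric(missingness))
}
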