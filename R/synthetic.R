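# Synthetic movement data with analytic ground truth.
#
# The generator uses a stationary isotropic Ornstein-Uhlenbeck (OU) process
# per pack. Its stationary law is a circular bivariate normal, so isopleth
# radii and disc-overlap fractions have closed forms that serve as oracles
# for the kernel estimators downstream.

# Deterministic 31-bit substream seed from a global seed and a label, so
# adding a pack never perturbs another pack's track.
.substreamSeed <- function(seed, id) {
  bytes <- utf8ToInt(paste0(seed, ":", id))
  h <- 2166136261
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Scheduled fix timestamps of a FixSchedule
#'
#' Expands a [FixSchedule-class] into the full vector of scheduled fix
#' times (UTC): the morning fix and the fix `intervalHours` later, for each
#' day of the window.
#'
#' @param schedule a [FixSchedule-class].
#' @return POSIXct vector of scheduled slots, sorted.
#' @export
scheduleSlots <- function(schedule) {
  stopifnot(is(schedule, "FixSchedule"))
  days <- seq(schedule@windowStart, schedule@windowEnd, by = "day")
  morning <- as.POSIXct(paste(days, "00:00:00"), tz = "UTC") +
    schedule@morningHour * 3600
  sort(c(morning, morning + schedule@intervalHours * 3600))
}

#' Simulate one pack's GPS track under stationary OU movement
#'
#' Positions evolve independently per axis by the exact OU transition
#' `x' = mu + (x - mu) * exp(-dt/tau) + N(0, sigma^2 * (1 - exp(-2 dt/tau)))`,
#' started from the stationary law `N(mu, sigma^2)`, so every fix is
#' marginally normal about the territory centre regardless of the schedule.
#' Scheduled fixes are then dropped independently with the schedule's
#' missingness probability.
#'
#' @param scenario a [PackScenario-class] (centre and sigma in km).
#' @param schedule a [FixSchedule-class].
#' @param seed integer seed for this pack's substream.
#' @return a [FixSeries-class] with coordinates in metres.
#' @examples
#' sc <- packScenario("A", center = c(0, 0), sigma = 5)
#' tr <- simulatePackTrack(sc, fixSchedule(missingness = 0), seed = 1)
#' nFixes(tr)
#' @export
simulatePackTrack <- function(scenario, schedule, seed = 1L) {
  stopifnot(is(scenario, "PackScenario"), is(schedule, "FixSchedule"))
  validObject(scenario); validObject(schedule)
  slots <- scheduleSlots(schedule)
  if (length(slots) == 0L) stop("empty schedule")
  set.seed(.substreamSeed(seed, scenario@packId))
  keep <- stats::runif(length(slots)) >= schedule@missingness
  dth <- diff(as.numeric(slots)) / 3600       # hours between slots
  rho <- exp(-dth / scenario@tau)
  n <- length(slots)
  x <- y <- numeric(n)
  x[1] <- stats::rnorm(1, 0, scenario@sigma)
  y[1] <- stats::rnorm(1, 0, scenario@sigma)
  if (n > 1L) {
    sdInnov <- scenario@sigma * sqrt(1 - rho^2)
    ex <- stats::rnorm(n - 1L, 0, sdInnov)
    ey <- stats::rnorm(n - 1L, 0, sdInnov)
    for (i in 2:n) {
      x[i] <- x[i - 1L] * rho[i - 1L] + ex[i - 1L]
      y[i] <- y[i - 1L] * rho[i - 1L] + ey[i - 1L]
    }
  }
  if (!any(keep)) stop("missingness removed every scheduled fix")
  fixes <- data.frame(
    timestamp = slots[keep],
    x = (scenario@center[1] + x[keep]) * 1000,
    y = (scenario@center[2] + y[keep]) * 1000)
  win <- as.POSIXct(paste(c(schedule@windowStart, schedule@windowEnd + 1),
                          "00:00:00"), tz = "UTC")
  fixSeries(scenario@packId, fixes, window = win)
}

#' Isopleth radius of a circular bivariate normal
#'
#' For an isotropic normal utilisation distribution with per-axis SD
#' `sigma`, the disc containing probability mass `level` has radius
#' `sigma * sqrt(-2 * log(1 - level))`.
#'
#' @param sigma per-axis SD (any length unit; radius returned in the same).
#' @param level probability in (0, 1).
#' @return the containment radius.
#' @examples
#' analyticIsoplethRadius(1, 0.95)  # 2.4477
#' @export
analyticIsoplethRadius <- function(sigma, level) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("sigma must be positive")
  if (any(!is.finite(level)) || any(level <= 0) || any(level >= 1))
    stop("level must be in (0, 1)")
  sigma * sqrt(-2 * log(1 - level))
}

# Intersection area of two discs with radii r1, r2 and centre distance d.
.lensArea <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  s <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  a1 + a2 - s
}

#' Analytic directional overlap of two stationary OU territories
#'
#' Under the isotropic OU model each pack's level-p isopleth is a disc
#' (radius from [analyticIsoplethRadius()]); the overlap region is the
#' circle-circle lens, and directional overlap is the lens area as a
#' percentage of each focal disc's area.
#'
#' @param dyad a [DyadScenario-class]; alternatively supply `sigmaA`,
#'   `sigmaB` and `separation` directly (all in the same unit).
#' @param level isopleth probability level in (0, 1).
#' @param sigmaA,sigmaB,separation scalar alternative to `dyad`.
#' @return named numeric of length 2: percentage of pack A's (then B's)
#'   isopleth area covered by the other pack's isopleth, in [0, 100].
#' @examples
#' analyticDirectionalOverlap(sigmaA = 5, sigmaB = 5, separation = 10,
#'                            level = 0.95)
#' @export
analyticDirectionalOverlap <- function(dyad = NULL, level = 0.95,
                                       sigmaA = NULL, sigmaB = NULL,
                                       separation = NULL) {
  if (!is.null(dyad)) {
    stopifnot(is(dyad, "DyadScenario"))
    sigmaA <- dyad@packA@sigma
    sigmaB <- dyad@packB@sigma
    separation <- sqrt(sum((dyad@packA@center - dyad@packB@center)^2))
  }
  if (any(!is.finite(c(sigmaA, sigmaB, separation))) ||
      sigmaA <= 0 || sigmaB <= 0 || separation < 0)
    stop("sigmas must be positive and separation non-negative")
  rA <- analyticIsoplethRadius(sigmaA, level)
  rB <- analyticIsoplethRadius(sigmaB, level)
  lens <- .lensArea(rA, rB, separation)
  c(aOnB = 100 * lens / (pi * rA^2), bOnA = 100 * lens / (pi * rB^2))
}

#' Generate a full synthetic study
#'
#' Simulates every pack referenced by the dyad scenarios under a shared fix
#' schedule and assembles the four tables the analysis pipeline consumes:
#' fixes, pack metadata, dyad definitions, and a truth table of analytic
#' directional overlaps at each isopleth level. Packs appearing in several
#' dyads are simulated once; each pack's random substream depends only on
#' the global seed and its own label.
#'
#' @param dyads list of [DyadScenario-class] objects.
#' @param schedule a [FixSchedule-class] shared by all packs.
#' @param seed global integer seed.
#' @param levels isopleth levels recorded in the truth table.
#' @param dir optional directory; when given, writes `fixes.csv`,
#'   `packs.csv`, `dyads.csv` and `truth.csv` there.
#' @return invisibly, a list with elements `fixes`, `packs`, `dyads`,
#'   `truth` (data.frames) and `tracks` (named list of [FixSeries-class]).
#' @export
generateStudy <- function(dyads, schedule = fixSchedule(), seed = 1L,
                          levels = c(0.5, 0.75, 0.95), dir = NULL) {
  stopifnot(is.list(dyads))
  for (d in dyads) stopifnot(is(d, "DyadScenario"))
  scen <- list()
  for (d in dyads) {
    for (p in list(d@packA, d@packB)) {
      id <- p@packId
      if (is.null(scen[[id]])) scen[[id]] <- p
      else if (!identical(scen[[id]], p))
        stop("duplicate pack id '", id, "' with conflicting parameters")
    }
  }
  ids <- names(scen)
  tracks <- list()
  fixRows <- vector("list", length(ids))
  packRows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    p <- scen[[ids[i]]]
    tr <- simulatePackTrack(p, schedule, seed = seed)
    tracks[[ids[i]]] <- tr
    f <- fixTable(tr)
    fixRows[[i]] <- data.frame(
      pack_id = ids[i],
      timestamp = format(f$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      x_m = f$x, y_m = f$y)
    packRows[[i]] <- data.frame(
      pack_id = ids[i], n_adults = p@nAdults, n_yearlings = p@nYearlings,
      n_pups = p@nPups, site = p@site)
  }
  fixes <- if (length(fixRows))
    do.call(rbind, c(fixRows, list(make.row.names = FALSE)))
  else data.frame(pack_id = character(), timestamp = character(),
                  x_m = numeric(), y_m = numeric())
  packs <- if (length(packRows))
    do.call(rbind, c(packRows, list(make.row.names = FALSE)))
  else data.frame(pack_id = character(), n_adults = integer(),
                  n_yearlings = integer(), n_pups = integer(),
                  site = character())
  dyadTab <- data.frame(
    focal_pack = vapply(dyads, function(d) d@packA@packId, character(1)),
    neighbour_pack = vapply(dyads, function(d) d@packB@packId, character(1)),
    relatedness = vapply(dyads, function(d) d@relatedness, character(1)),
    relationship_type = vapply(dyads, function(d) d@relationshipType,
                               character(1)))
  truthRows <- list()
  for (d in dyads) {
    for (lev in levels) {
      ov <- analyticDirectionalOverlap(d, level = lev)
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        focal_pack = c(d@packA@packId, d@packB@packId),
        neighbour_pack = c(d@packB@packId, d@packA@packId),
        level = lev, analytic_overlap_pct = unname(ov))
    }
  }
  truth <- if (length(truthRows))
    do.call(rbind, c(truthRows, list(make.row.names = FALSE)))
  else data.frame(focal_pack = character(), neighbour_pack = character(),
                  level = numeric(), analytic_overlap_pct = numeric())
  out <- list(fixes = fixes, packs = packs, dyads = dyadTab, truth = truth,
              tracks = tracks)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in c("fixes", "packs", "dyads", "truth"))
      utils::write.csv(out[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  invisible(out)
}

#' Simulate a stationary OU track of arbitrary length
#'
#' Validation-scale variant of [simulatePackTrack()]: `n` fixes at a fixed
#' sampling interval, no missingness and no schedule-window cap. Used to
#' drive large-sample oracle checks (containment, overlap convergence)
#' where the field protocol's four-month window would limit the fix count.
#'
#' @param scenario a [PackScenario-class].
#' @param n number of fixes.
#' @param intervalHours sampling interval.
#' @param start first timestamp (POSIXct or ISO string, UTC).
#' @param seed integer seed for this pack's substream.
#' @return a [FixSeries-class] in metres.
#' @export
simulateStationaryTrack <- function(scenario, n, intervalHours = 12,
                                    start = "2020-01-01 06:00:00",
                                    seed = 1L) {
  stopifnot(is(scenario, "PackScenario"))
  validObject(scenario)
  n <- as.integer(n)
  if (n < 1L) stop("n must be positive")
  set.seed(.substreamSeed(seed, scenario@packId))
  rho <- exp(-intervalHours / scenario@tau)
  sdInnov <- scenario@sigma * sqrt(1 - rho^2)
  x <- y <- numeric(n)
  x[1] <- stats::rnorm(1, 0, scenario@sigma)
  y[1] <- stats::rnorm(1, 0, scenario@sigma)
  if (n > 1L) {
    ex <- stats::rnorm(n - 1L, 0, sdInnov)
    ey <- stats::rnorm(n - 1L, 0, sdInnov)
    for (i in 2:n) {
      x[i] <- x[i - 1L] * rho + ex[i - 1L]
      y[i] <- y[i - 1L] * rho + ey[i - 1L]
    }
  }
  t0 <- as.POSIXct(start, tz = "UTC")
  fixes <- data.frame(
    timestamp = t0 + (seq_len(n) - 1L) * intervalHours * 3600,
    x = (scenario@center[1] + x) * 1000,
    y = (scenario@center[2] + y) * 1000)
  fixSeries(scenario@packId, fixes)
}
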