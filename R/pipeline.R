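# End-to-end orchestration: ingest (or simulate) -> two-per-day thinning ->
# denning exclusion -> kernel UDs and isopleths -> dyadic overlap, intensity
# and occupancy tables -> rank tests -> AICc mixed-model inference -> report
# files and a run manifest.

#' Pipeline configuration
#'
#' Collects every knob of the analysis run. Provide either the three input
#' CSV paths or a synthetic study (the output of [generateStudy()] /
#' [makeFixtures()]), not neither.
#'
#' @param fixes,packs,dyads CSV paths (see [readFixesCsv()] for schemas).
#' @param study alternatively, an in-memory study list from
#'   [generateStudy()].
#' @param window optional length-2 Date vector restricting the analysis
#'   window; fixes outside it are dropped before thinning.
#' @param exclusions named list of length-2 Date vectors: per-pack denning
#'   windows to exclude.
#' @param levels isopleth levels, strictly ascending.
#' @param cellSizeM raster cell size in metres (`NULL` = automatic).
#' @param morningCandidates clock hours accepted for the first daily fix.
#' @param utcOffsetHours offset added to the candidate clock hours to map
#'   local fix times to UTC.
#' @param cumWeight cumulative Akaike-weight threshold for model averaging.
#' @param minFixes packs with fewer post-filter fixes are skipped with a
#'   warning (the bandwidth needs variance; 5 is a degeneracy guard).
#' @param seed integer seed (reserved for synthetic inputs).
#' @param outDir output directory; `NULL` runs in memory only.
#' @param writeRasters write per-pack ESRI ASCII UD grids (can be bulky).
#' @return a list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(fixes = NULL, packs = NULL, dyads = NULL,
                           study = NULL, window = NULL,
                           exclusions = list(),
                           levels = c(0.5, 0.75, 0.95), cellSizeM = NULL,
                           morningCandidates = c(5, 6, 6.5),
                           utcOffsetHours = 0, cumWeight = 0.95,
                           minFixes = 5L, seed = 1L, outDir = NULL,
                           writeRasters = TRUE) {
  havePaths <- !is.null(fixes) && !is.null(packs) && !is.null(dyads)
  if (!havePaths && is.null(study))
    stop("provide input CSV paths (fixes, packs, dyads) or a synthetic study")
  if (any(diff(levels) <= 0)) stop("levels must be strictly ascending")
  structure(list(fixes = fixes, packs = packs, dyads = dyads, study = study,
                 window = window, exclusions = exclusions, levels = levels,
                 cellSizeM = cellSizeM,
                 morningCandidates = morningCandidates,
                 utcOffsetHours = utcOffsetHours, cumWeight = cumWeight,
                 minFixes = as.integer(minFixes), seed = as.integer(seed),
                 outDir = outDir, writeRasters = writeRasters),
            class = "pipelineConfig")
}

# Scenario builders for the named fixture presets. Chains of packs per
# study site; each dyad's centre separation is drawn relative to the mean
# 95% isopleth radius of its two packs: related U(0.8, 1.6) x R95,
# unrelated U(1.6, 2.4) x R95 ("null" draws all classes from U(1.4, 2.0)).
.buildSiteChain <- function(idPrefix, nPacks, relatednessOfDyad, site,
                            nullEffects = FALSE) {
  sig <- stats::runif(nPacks, 3.5, 6)
  packs <- vector("list", nPacks)
  centers <- matrix(0, nPacks, 2)
  heading <- stats::runif(1, 0, 2 * pi)
  packs[[1]] <- packScenario(
    paste0(idPrefix, 1), center = c(0, 0), sigma = sig[1], tau = 24,
    nAdults = 2L + stats::rpois(1, 3), nYearlings = stats::rpois(1, 2),
    nPups = stats::rpois(1, 4), site = site)
  dyads <- list()
  for (i in 2:nPacks) {
    rel <- relatednessOfDyad[i - 1L]
    r95 <- analyticIsoplethRadius(mean(sig[c(i - 1L, i)]), 0.95)
    sep <- if (nullEffects) stats::runif(1, 1.4, 2.0) * r95
           else if (rel == "related") stats::runif(1, 0.8, 1.6) * r95
           else stats::runif(1, 1.6, 2.4) * r95
    heading <- heading + stats::runif(1, -pi / 4, pi / 4)
    centers[i, ] <- centers[i - 1L, ] + sep * c(cos(heading), sin(heading))
    packs[[i]] <- packScenario(
      paste0(idPrefix, i), center = centers[i, ], sigma = sig[i], tau = 24,
      nAdults = 2L + stats::rpois(1, 3), nYearlings = stats::rpois(1, 2),
      nPups = stats::rpois(1, 4), site = site)
    dyads[[i - 1L]] <- list(a = i - 1L, b = i, relatedness = rel)
  }
  list(packs = packs, dyads = dyads)
}

.presetScenarios <- function(preset, seed) {
  set.seed(.substreamSeed(seed, paste0("design:", preset)))
  mkDyads <- function(chain, extra = list()) {
    ds <- c(chain$dyads, extra)
    lapply(ds, function(d) list(packA = chain$packs[[d$a]],
                                packB = chain$packs[[d$b]],
                                relatedness = d$relatedness))
  }
  assignTypes <- function(dyads, nFF, nMF) {
    relIdx <- which(vapply(dyads, function(d) d$relatedness == "related",
                           logical(1)))
    types <- sample(c(rep("female-female", nFF), rep("male-female", nMF)))
    for (i in seq_along(relIdx)) dyads[[relIdx[i]]]$type <- types[i]
    dyads
  }
  if (preset == "tiny") {
    ch <- .buildSiteChain("T", 3L, c("related", "unrelated"), "tiny")
    dy <- assignTypes(mkDyads(ch), 1L, 0L)
  } else if (preset %in% c("paper_like", "null")) {
    nullEff <- preset == "null"
    relB <- sample(c(rep("related", 8), rep("unrelated", 4)))
    relZ <- sample(c(rep("related", 4), rep("unrelated", 3)))
    chB <- .buildSiteChain("B", 13L, relB, "Botswana", nullEff)
    chZ <- .buildSiteChain("Z", 8L, relZ, "Zimbabwe", nullEff)
    # the eighth Zimbabwe dyad closes the chain between packs 1 and 3
    dy <- c(mkDyads(chB),
            mkDyads(chZ, extra = list(list(a = 1L, b = 3L,
                                           relatedness = "unrelated"))))
    dy <- assignTypes(dy, 10L, 2L)
  } else {
    stop("unknown preset '", preset,
         "'; available: paper_like, tiny, null")
  }
  lapply(dy, function(d) dyadScenario(
    d$packA, d$packB, d$relatedness,
    if (d$relatedness == "related") d$type else NA_character_))
}

#' Build a named synthetic fixture study
#'
#' Presets: `paper_like` — 21 packs in two study-site chains with 20 dyads
#' (12 related, 10 of them female-female and 2 male-female; 8 unrelated),
#' the design shape of the motivating field study; `tiny` — 3 packs and 2
#' dyads for smoke tests; `null` — the `paper_like` layout but with centre
#' separations drawn identically for related and unrelated labels, so
#' relatedness has no true effect.
#'
#' @param preset one of `"paper_like"`, `"tiny"`, `"null"`.
#' @param seed global integer seed.
#' @param schedule a [FixSchedule-class]; the default emulates a 122-day
#'   post-denning window at two fixes per day with 11.3% dropout.
#' @param dir optional directory to write the four CSVs to.
#' @return the [generateStudy()] bundle, plus element `scenarios`.
#' @export
makeFixtures <- function(preset = c("paper_like", "tiny", "null"),
                         seed = 1L, schedule = fixSchedule(), dir = NULL) {
  preset <- match.arg(preset)
  scen <- .presetScenarios(preset, seed)
  study <- generateStudy(scen, schedule = schedule, seed = seed, dir = dir)
  study$scenarios <- scen
  invisible(study)
}

#' Run the full overlap analysis pipeline
#'
#' Executes ingest, two-per-day thinning, denning exclusion, kernel UD
#' estimation, isopleth extraction, dyadic overlap / exclusive-kernel
#' intensity / overlap-zone occupancy computation, rank-based group
#' comparisons, and AICc mixed-model inference. Packs with fewer than
#' `minFixes` usable fixes are skipped with a warning; dyads that lose a
#' member are dropped with a warning. Given the same config and seed the
#' run is deterministic.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list: `series`, `uds`, `isos` (per pack),
#'   `overlap`, `occupancy`, `intensity` (tables), `stats` (rank-test
#'   report), `models` (`modelSet`, `averagedModel`, predictions) and
#'   `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  warningsLog <- character()
  note <- function(msg) {
    warningsLog <<- c(warningsLog, msg)
    warning(msg, call. = FALSE)
  }

  ## -- ingest -------------------------------------------------------------
  if (!is.null(config$study)) {
    fixes <- config$study$fixes
    packs <- config$study$packs
    dyads <- config$study$dyads
  } else {
    fixes <- readFixesCsv(config$fixes)
    packs <- readPacksCsv(config$packs)
    dyads <- readDyadsCsv(config$dyads)
  }
  nInput <- nrow(fixes)
  candidates <- config$morningCandidates + config$utcOffsetHours

  ## -- per-pack fix processing -------------------------------------------
  ids <- sort(unique(fixes$pack_id))
  series <- list(); skipped <- character()
  counts <- data.frame(pack_id = ids, raw = NA_integer_, used = NA_integer_)
  for (i in seq_along(ids)) {
    id <- ids[i]
    raw <- fixes[fixes$pack_id == id,
                 c("timestamp", "x_m", "y_m")]
    names(raw) <- c("timestamp", "x", "y")
    counts$raw[i] <- nrow(raw)
    s <- tryCatch({
      s <- subsampleTwoDaily(raw, packId = id,
                             morningCandidates = candidates)
      if (!is.null(config$window)) {
        w <- as.POSIXct(paste(as.Date(config$window), c("00:00:00",
                                                        "23:59:59")),
                        tz = "UTC")
        f <- fixTable(s)
        keep <- f$timestamp >= w[1] & f$timestamp <= w[2]
        if (!any(keep)) stop("no fixes inside the analysis window")
        s <- fixSeries(id, f[keep, , drop = FALSE])
      }
      ex <- config$exclusions[[id]]
      if (!is.null(ex)) s <- excludeWindow(s, ex[1], ex[2])
      s
    }, error = function(e) {
      note(paste0("pack '", id, "' skipped: ", conditionMessage(e)))
      NULL
    })
    if (!is.null(s) && nFixes(s) < config$minFixes) {
      note(paste0("pack '", id, "' skipped: only ", nFixes(s),
                  " usable fixes (< ", config$minFixes, ")"))
      s <- NULL
    }
    if (is.null(s)) skipped <- c(skipped, id)
    else {
      series[[id]] <- s
      counts$used[i] <- nFixes(s)
    }
  }

  dropDyad <- dyads$focal_pack %in% skipped |
    dyads$neighbour_pack %in% skipped
  if (any(dropDyad)) {
    note(paste0(sum(dropDyad), " dyad(s) dropped: member pack skipped"))
    dyads <- dyads[!dropDyad, , drop = FALSE]
  }

  ## -- kernels and isopleths ---------------------------------------------
  uds <- lapply(series, estimateUD, cellSizeM = config$cellSizeM)
  isos <- lapply(uds, extractIsopleths, levels = config$levels)

  ## -- dyadic metrics ------------------------------------------------------
  dt <- dyadTable(isos, series, packs, dyads, levels = config$levels)
  intensity <- do.call(rbind, c(unname(
    lapply(names(series), function(id)
      utilisationIntensity(series[[id]], isos[[id]]))),
    list(make.row.names = FALSE)))

  ## -- rank statistics -----------------------------------------------------
  stats <- .pipelineStats(dt, intensity, config$levels)

  ## -- mixed models --------------------------------------------------------
  models <- NULL
  lev95 <- max(config$levels)
  obs <- dt$overlap[dt$overlap$level == lev95, , drop = FALSE]
  if (nrow(obs) >= 10L && length(unique(obs$relatedness)) == 2L) {
    obs <- data.frame(focal_pack = obs$focal_pack,
                      relatedness = obs$relatedness,
                      pack_size_ratio = obs$pack_size_ratio,
                      pct_overlap_95 = obs$pct_of_focal)
    models <- tryCatch({
      ms <- dredgeModels(obs)
      avg <- modelAverage(ms, cumWeight = config$cumWeight)
      list(observations = obs, modelSet = ms, averaged = avg,
           predictions = predictInteractionSurface(avg))
    }, error = function(e) {
      note(paste0("model stage skipped: ", conditionMessage(e)))
      NULL
    })
  } else {
    note("model stage skipped: too few directional observations")
  }

  manifest <- list(
    config_hash = .configHash(unclass(config)[setdiff(names(config),
                                                      c("study", "outDir"))]),
    package_version = as.character(utils::packageVersion("rangeOverlap")),
    n_input_fixes = nInput,
    pack_counts = counts,
    skipped_packs = skipped,
    n_dyads_analysed = nrow(dyads),
    n_overlap_rows = nrow(dt$overlap),
    warnings = warningsLog)

  result <- list(series = series, uds = uds, isos = isos,
                 overlap = dt$overlap, occupancy = dt$occupancy,
                 intensity = intensity, stats = stats, models = models,
                 manifest = manifest)
  if (!is.null(config$outDir)) .writeBundle(result, dyads, config)
  invisible(result)
}

# Rank-test report: related vs unrelated directional overlap at each level,
# occupancy comparison, and the intensity comparison across kernel classes.
.pipelineStats <- function(dt, intensity, levels) {
  rows <- list(); tests <- list()
  addRow <- function(id, method, stat, statName, df, p, n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = id, method = method, statistic = stat,
      statistic_name = statName, df = df, p_value = p,
      n = paste(n, collapse = "/"))
  }
  ov <- dt$overlap
  for (lev in levels) {
    a <- ov$pct_of_focal[ov$level == lev & ov$relatedness == "related"]
    b <- ov$pct_of_focal[ov$level == lev & ov$relatedness == "unrelated"]
    if (length(a) && length(b)) {
      mw <- mannWhitney(a, b)
      tests[[paste0("overlap_", lev * 100)]] <- mw
      addRow(sprintf("overlap_%d_related_vs_unrelated", round(lev * 100)),
             mw$method, mw$U, "U", NA, mw$p_value, c(mw$n1, mw$n2))
    }
  }
  occ <- dt$occupancy
  a <- occ$proportion_time[occ$relatedness == "related"]
  b <- occ$proportion_time[occ$relatedness == "unrelated"]
  if (length(a) && length(b)) {
    mw <- mannWhitney(a, b)
    tests$occupancy <- mw
    addRow("occupancy_related_vs_unrelated", mw$method, mw$U, "U", NA,
           mw$p_value, c(mw$n1, mw$n2))
  }
  groups <- split(intensity$intensity[!is.na(intensity$intensity)],
                  intensity$level[!is.na(intensity$intensity)])
  tukey <- NULL
  if (length(groups) >= 2L && all(lengths(groups) > 0L)) {
    kw <- kruskalWallis(groups)
    tests$intensity <- kw
    addRow("intensity_by_kernel", kw$method, kw$H, "H", kw$df, kw$p_value,
           lengths(groups))
    tukey <- pairwiseTukeyOnRanks(groups)
  }
  list(report = if (length(rows))
         do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL,
       tests = tests, intensity_pairwise = tukey)
}

.writeBundle <- function(result, dyads, config) {
  out <- config$outDir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  wcsv <- function(x, nm) if (!is.null(x))
    utils::write.csv(x, file.path(out, nm), row.names = FALSE)
  wcsv(result$overlap, "overlap_long.csv")
  wcsv(result$occupancy, "occupancy.csv")
  wcsv(result$intensity, "intensity.csv")
  wcsv(result$stats$report, "stats_report.csv")
  wcsv(result$stats$intensity_pairwise, "intensity_pairwise.csv")
  if (!is.null(result$models)) {
    wcsv(result$models$modelSet$table, "model_table.csv")
    wcsv(result$models$averaged$table, "averaged_effects.csv")
    wcsv(result$models$predictions, "prediction_surface.csv")
  }
  gjDir <- file.path(out, "geojson")
  if (!dir.exists(gjDir)) dir.create(gjDir)
  for (id in names(result$isos)) {
    if (isTRUE(config$writeRasters))
      writeEsriAscii(result$uds[[id]],
                     file.path(out, paste0("ud_", id, ".asc")))
    writeIsoplethGeoJSON(result$isos[[id]],
                         file.path(gjDir, paste0("isopleths_", id, ".geojson")))
  }
  lev95 <- max(config$levels)
  for (r in seq_len(nrow(dyads))) {
    a <- dyads$focal_pack[r]; b <- dyads$neighbour_pack[r]
    zone <- overlapZoneMask(result$isos[[a]], result$isos[[b]], lev95)
    writeZoneGeoJSON(zone, a, b, lev95,
                     file.path(gjDir, paste0("zone_", a, "_", b, ".geojson")))
  }
  jsonlite::write_json(result$manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out)
}
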