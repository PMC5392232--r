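# Dyadic overlap metrics: directional same-level kernel overlap, exclusive
# kernels with utilisation intensity, and time spent in the 95% overlap
# zone. All intersections are raster intersections on a shared grid so that
# areas and overlaps are mutually consistent.

# Resample an isopleth mask onto a shared grid defined by origin/cellSize
# and cell centre coordinates; membership of a shared cell is membership of
# its centre in the source mask (half-open cell rule).
.resampleMask <- function(iso, level, xc, yc) {
  mask <- isoMask(iso, level)
  ix <- floor((xc - iso@origin[1]) / iso@cellSize) + 1L
  iy <- floor((yc - iso@origin[2]) / iso@cellSize) + 1L
  okx <- ix >= 1L & ix <= nrow(mask)
  oky <- iy >= 1L & iy <= ncol(mask)
  out <- matrix(FALSE, length(xc), length(yc))
  if (any(okx) && any(oky))
    out[okx, oky] <- mask[ix[okx], iy[oky], drop = FALSE]
  out
}

# Shared grid covering both isopleth sets at the finest common cell size.
.sharedGrid <- function(isoA, isoB) {
  cell <- min(isoA@cellSize, isoB@cellSize)
  extent <- function(iso) {
    d <- dim(iso@masks[[length(iso@masks)]])
    c(iso@origin[1], iso@origin[1] + d[1] * iso@cellSize,
      iso@origin[2], iso@origin[2] + d[2] * iso@cellSize)
  }
  ea <- extent(isoA); eb <- extent(isoB)
  x0 <- min(ea[1], eb[1]); x1 <- max(ea[2], eb[2])
  y0 <- min(ea[3], eb[3]); y1 <- max(ea[4], eb[4])
  nx <- ceiling((x1 - x0) / cell)
  ny <- ceiling((y1 - y0) / cell)
  list(origin = c(x0, y0), cell = cell,
       xc = x0 + (seq_len(nx) - 0.5) * cell,
       yc = y0 + (seq_len(ny) - 0.5) * cell)
}

#' Directional kernel overlap of a dyad at one isopleth level
#'
#' Computes the raster intersection of the two packs' same-level isopleths
#' on a shared grid (union bounding box, finest common cell size) and
#' expresses it as a percentage of each focal pack's kernel area — two
#' values per dyad, since a small pack overlapped by a large neighbour
#' loses proportionally more of its range than the reverse.
#'
#' @param isoFocal,isoNeighbour [IsoplethSet-class] objects of the two
#'   packs, both containing `level`.
#' @param level isopleth probability level present in both sets.
#' @return data.frame with two rows (each pack as focal): `focal_pack`,
#'   `neighbour_pack`, `level`, `overlap_area_km2`, `pct_of_focal`.
#' @export
directionalOverlap <- function(isoFocal, isoNeighbour, level = 0.95) {
  stopifnot(is(isoFocal, "IsoplethSet"), is(isoNeighbour, "IsoplethSet"))
  if (!level %in% isoLevels(isoFocal) || !level %in% isoLevels(isoNeighbour))
    stop("both isopleth sets must contain level ", level)
  g <- .sharedGrid(isoFocal, isoNeighbour)
  mA <- .resampleMask(isoFocal, level, g$xc, g$yc)
  mB <- .resampleMask(isoNeighbour, level, g$xc, g$yc)
  ca <- g$cell^2 / 1e6
  inter <- sum(mA & mB) * ca
  areaA <- sum(mA) * ca
  areaB <- sum(mB) * ca
  data.frame(
    focal_pack = c(packId(isoFocal), packId(isoNeighbour)),
    neighbour_pack = c(packId(isoNeighbour), packId(isoFocal)),
    level = level,
    overlap_area_km2 = inter,
    pct_of_focal = c(if (areaA > 0) 100 * inter / areaA else 0,
                     if (areaB > 0) 100 * inter / areaB else 0))
}

#' Exclusive kernels of a nested isopleth set
#'
#' Splits the outermost kernel into the annuli between consecutive
#' isopleths: the exclusive 50% kernel is the 50% kernel itself, the
#' exclusive 75% kernel is the 75% minus the 50%, and the exclusive 95%
#' kernel is the 95% minus the 75%. The exclusive areas partition the 95%
#' kernel, so they sum exactly to its area on the raster.
#'
#' @param iso an [IsoplethSet-class] with nested masks.
#' @return list with `levels`, `masks` (list of logical matrices) and
#'   `areaKm2` (numeric), in increasing level order.
#' @export
exclusiveKernels <- function(iso) {
  stopifnot(is(iso, "IsoplethSet"))
  validObject(iso)   # nesting is an upstream invariant
  k <- length(iso@levels)
  masks <- vector("list", k)
  for (i in seq_len(k)) {
    masks[[i]] <- if (i == 1L) iso@masks[[1L]]
                  else iso@masks[[i]] & !iso@masks[[i - 1L]]
  }
  ca <- iso@cellSize^2 / 1e6
  list(levels = iso@levels, masks = masks,
       areaKm2 = vapply(masks, sum, numeric(1)) * ca)
}

#' Kernel-specific utilisation intensity
#'
#' The percentage of a pack's fixes (equal time units) falling in each
#' exclusive kernel, divided by that kernel's area in square kilometres:
#' percent of time per square kilometre. High values in the 50% kernel and
#' low values in the outer 95% annulus quantify how much more intensively
#' the core is used than the periphery.
#'
#' @param series the pack's [FixSeries-class] (the same post-thinning,
#'   post-exclusion set used for the UD).
#' @param iso the pack's [IsoplethSet-class].
#' @return data.frame with one row per level: `pack_id`, `level`,
#'   `exclusive_area_km2`, `pct_time`, `intensity` (percent per km2;
#'   `NA` where the exclusive area is zero).
#' @export
utilisationIntensity <- function(series, iso) {
  stopifnot(is(series, "FixSeries"), is(iso, "IsoplethSet"))
  f <- fixTable(series)
  if (nrow(f) == 0L) stop("empty fix series")
  ex <- exclusiveKernels(iso)
  pct <- vapply(ex$masks, function(m)
    100 * sum(.pointsInMask(f$x, f$y, m, iso@origin, iso@cellSize)) / nrow(f),
    numeric(1))
  intensity <- ifelse(ex$areaKm2 > 0, pct / ex$areaKm2, NA_real_)
  data.frame(pack_id = packId(series), level = ex$levels,
             exclusive_area_km2 = ex$areaKm2, pct_time = pct,
             intensity = intensity)
}

#' Proportion of time spent in the 95% overlap zone
#'
#' Treats each fix as an equal unit of time and returns the fraction of the
#' focal pack's fixes lying inside the intersection of the two packs' 95%
#' isopleths (a fix is in the zone when it is inside both packs' masks).
#'
#' @param seriesFocal the focal pack's [FixSeries-class].
#' @param isoFocal,isoNeighbour the two packs' [IsoplethSet-class] objects.
#' @param level isopleth level defining the zone (default 0.95).
#' @return data.frame row: `focal_pack`, `neighbour_pack`,
#'   `proportion_time` in [0, 1].
#' @export
timeInOverlapZone <- function(seriesFocal, isoFocal, isoNeighbour,
                              level = 0.95) {
  stopifnot(is(seriesFocal, "FixSeries"), is(isoFocal, "IsoplethSet"),
            is(isoNeighbour, "IsoplethSet"))
  f <- fixTable(seriesFocal)
  if (nrow(f) == 0L) stop("empty focal fix series")
  inF <- .pointsInMask(f$x, f$y, isoMask(isoFocal, level),
                       isoFocal@origin, isoFocal@cellSize)
  inN <- .pointsInMask(f$x, f$y, isoMask(isoNeighbour, level),
                       isoNeighbour@origin, isoNeighbour@cellSize)
  data.frame(focal_pack = packId(seriesFocal),
             neighbour_pack = packId(isoNeighbour),
             proportion_time = mean(inF & inN))
}

#' Assemble the long dyad table of a study
#'
#' Computes every dyad's directional overlaps at each level plus the 95%
#' overlap-zone occupancy of both members, joined with relatedness and pack
#' sizes. Two rows per dyad per level (each pack once as focal); rows are
#' ordered by dyad, then level, then direction.
#'
#' @param isos named list of [IsoplethSet-class], one per pack.
#' @param seriesList named list of [FixSeries-class], one per pack.
#' @param packs data.frame with `pack_id`, `n_adults`, `n_yearlings`,
#'   `n_pups` (pack size is their sum).
#' @param dyads data.frame with `focal_pack`, `neighbour_pack`,
#'   `relatedness` (and optionally `relationship_type`).
#' @param levels isopleth levels to report.
#' @return list of data.frames: `overlap` (directional records) and
#'   `occupancy` (95% overlap-zone time proportions).
#' @export
dyadTable <- function(isos, seriesList, packs, dyads,
                      levels = c(0.5, 0.75, 0.95)) {
  need <- unique(c(dyads$focal_pack, dyads$neighbour_pack))
  missing <- setdiff(need, names(isos))
  if (length(missing))
    stop("dyads reference packs without fitted isopleths: ",
         paste(missing, collapse = ", "))
  sizeOf <- function(id) {
    i <- match(id, packs$pack_id)
    if (is.na(i)) stop("pack '", id, "' absent from pack metadata")
    packs$n_adults[i] + packs$n_yearlings[i] + packs$n_pups[i]
  }
  ovRows <- list(); occRows <- list()
  for (r in seq_len(nrow(dyads))) {
    a <- dyads$focal_pack[r]; b <- dyads$neighbour_pack[r]
    rel <- dyads$relatedness[r]
    sa <- sizeOf(a); sb <- sizeOf(b)
    for (lev in sort(levels)) {
      ov <- directionalOverlap(isos[[a]], isos[[b]], level = lev)
      ov$relatedness <- rel
      ov$focal_size <- c(sa, sb)
      ov$neighbour_size <- c(sb, sa)
      ov$pack_size_ratio <- ov$focal_size / ov$neighbour_size
      ovRows[[length(ovRows) + 1L]] <- ov
    }
    occA <- timeInOverlapZone(seriesList[[a]], isos[[a]], isos[[b]])
    occB <- timeInOverlapZone(seriesList[[b]], isos[[b]], isos[[a]])
    occ <- rbind(occA, occB)
    occ$relatedness <- rel
    occRows[[length(occRows) + 1L]] <- occ
  }
  emptyOv <- data.frame(focal_pack = character(), neighbour_pack = character(),
                        level = numeric(), overlap_area_km2 = numeric(),
                        pct_of_focal = numeric(), relatedness = character(),
                        focal_size = numeric(), neighbour_size = numeric(),
                        pack_size_ratio = numeric())
  emptyOcc <- data.frame(focal_pack = character(), neighbour_pack = character(),
                         proportion_time = numeric(), relatedness = character())
  list(overlap = if (length(ovRows))
         do.call(rbind, c(ovRows, list(make.row.names = FALSE))) else emptyOv,
       occupancy = if (length(occRows))
         do.call(rbind, c(occRows, list(make.row.names = FALSE))) else emptyOcc)
}

#' Shared 95% overlap-zone mask of a dyad
#'
#' Utility for export/inspection: the raster intersection of two packs'
#' isopleths at a level, on the shared grid.
#'
#' @inheritParams directionalOverlap
#' @return list with `origin`, `cell` (m) and logical `mask`.
#' @export
overlapZoneMask <- function(isoFocal, isoNeighbour, level = 0.95) {
  g <- .sharedGrid(isoFocal, isoNeighbour)
  mA <- .resampleMask(isoFocal, level, g$xc, g$yc)
  mB <- .resampleMask(isoNeighbour, level, g$xc, g$yc)
  list(origin = g$origin, cell = g$cell, mask = mA & mB)
}
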