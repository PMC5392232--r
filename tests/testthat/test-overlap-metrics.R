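# Directional overlap, exclusive kernels, utilisation intensity and
# overlap-zone occupancy.

test_that("directional overlap handles identity and disjoint ranges", {
  self <- directionalOverlap(oracleIsoA, oracleIsoA, 0.95)
  expect_equal(self$pct_of_focal, c(100, 100))
  far <- packScenario("F", c(500, 500), 4)
  isoFar <- extractIsopleths(estimateUD(simulateStationaryTrack(far, 300,
                                                                seed = 3)))
  disj <- directionalOverlap(oracleIsoA, isoFar, 0.95)
  expect_equal(disj$pct_of_focal, c(0, 0))
  expect_equal(disj$overlap_area_km2, c(0, 0))
  expect_error(directionalOverlap(oracleIsoA, isoFar, 0.9), "level")
})

test_that("estimated 95% overlap matches the circle-lens oracle", {
  truth <- analyticDirectionalOverlap(sigmaA = 5, sigmaB = 5,
                                      separation = 10, level = 0.95)
  est <- directionalOverlap(oracleIsoA, oracleIsoB, 0.95)
  expect_lt(abs(est$pct_of_focal[1] - truth[["aOnB"]]), 5)
  expect_lt(abs(est$pct_of_focal[2] - truth[["bOnA"]]), 5)
  # equal-sigma packs: near-symmetric within Monte-Carlo error
  expect_lt(abs(est$pct_of_focal[1] - est$pct_of_focal[2]), 5)
})

test_that("overlap area is monotone across nested levels", {
  areas <- vapply(c(0.5, 0.75, 0.95), function(lev)
    directionalOverlap(oracleIsoA, oracleIsoB, lev)$overlap_area_km2[1],
    numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("estimated overlap decreases with centre separation", {
  seps <- c(5, 12, 20, 28)
  ovs <- vapply(seps, function(d) {
    sc <- packScenario(paste0("S", d), c(d, 0), 5)
    iso <- extractIsopleths(estimateUD(simulateStationaryTrack(sc, 600,
                                                               seed = 11)))
    directionalOverlap(oracleIsoA, iso, 0.95)$pct_of_focal[1]
  }, numeric(1))
  expect_true(all(diff(ovs) < 2))   # monotone within small estimation noise
  expect_gt(ovs[1], ovs[4])
})

test_that("exclusive kernels partition the 95% kernel exactly", {
  ex <- exclusiveKernels(oracleIsoA)
  expect_equal(sum(ex$areaKm2), isoArea(oracleIsoA, 0.95))
  expect_false(any(ex$masks[[1]] & ex$masks[[2]]))
  expect_false(any(ex$masks[[2]] & ex$masks[[3]]))
  # degenerate nesting: identical masks leave the outer annuli empty
  m <- isoMask(oracleIsoA, 0.5)
  iso1 <- new("IsoplethSet", packId = "deg", levels = c(0.5, 0.75, 0.95),
              masks = list(m, m, m),
              areaKm2 = rep(sum(m) * cellSize(oracleIsoA)^2 / 1e6, 3),
              thresholds = rep(0, 3), origin = oracleIsoA@origin,
              cellSize = cellSize(oracleIsoA),
              polygons = list(list(), list(), list()))
  exd <- exclusiveKernels(iso1)
  expect_equal(exd$areaKm2[2:3], c(0, 0))
  expect_equal(exd$areaKm2[1], sum(m) * cellSize(oracleIsoA)^2 / 1e6)
})

test_that("circular-normal exclusive areas follow the annulus ratio", {
  # E95/E50 area ratio = (ln 0.05 - ln 0.25) / ln 0.5 for the normal UD
  sig <- 5000; cell <- 100
  xc <- yc <- seq(-4 * sig + cell / 2, 4 * sig, by = cell)
  d <- outer(dnorm(xc, 0, sig), dnorm(yc, 0, sig))
  d <- d / (sum(d) * cell^2)
  ud <- new("UtilizationDistribution", packId = "N",
            origin = c(-4 * sig, -4 * sig), cellSize = cell, density = d,
            bandwidth = c(1, 1), nFixes = 1L)
  ex <- exclusiveKernels(extractIsopleths(ud))
  expect_equal(ex$areaKm2[3] / ex$areaKm2[1],
               (log(0.05) - log(0.25)) / log(0.5), tolerance = 0.02)
})

test_that("utilisation intensity is time share per square kilometre", {
  # half the fixes in a 50 km2 core: intensity exactly 1 %/km2
  cell <- 1000
  m50 <- matrix(FALSE, 20, 20); m50[3:9, 3:10] <- TRUE   # 56 cells
  m75 <- m50; m75[11:14, 3:10] <- TRUE
  m95 <- m75; m95[15:18, 3:10] <- TRUE
  iso <- new("IsoplethSet", packId = "X", levels = c(0.5, 0.75, 0.95),
             masks = list(m50, m75, m95),
             areaKm2 = c(sum(m50), sum(m75), sum(m95)) * cell^2 / 1e6,
             thresholds = c(3, 2, 1), origin = c(0, 0), cellSize = cell,
             polygons = list(list(), list(), list()))
  inPt <- c(5.5, 5.5) * cell   # inside the core
  outPt <- c(19.5, 19.5) * cell  # outside all kernels
  n <- 56 * 2
  f <- data.frame(
    timestamp = seq(as.POSIXct("2023-10-01", tz = "UTC"), by = 43200,
                    length.out = n),
    x = rep(c(inPt[1], outPt[1]), n / 2),
    y = rep(c(inPt[2], outPt[2]), n / 2))
  s <- fixSeries("X", f)
  it <- utilisationIntensity(s, iso)
  expect_equal(it$pct_time[1], 50)
  expect_equal(it$exclusive_area_km2[1], 56)
  expect_equal(it$intensity[1], 50 / 56)
  # all fixes outside the 95% kernel: zero shares, zero intensities
  fOut <- transform(f, x = x + 1e6)
  itOut <- utilisationIntensity(fixSeries("X", fOut), iso)
  expect_equal(itOut$pct_time, c(0, 0, 0))
  expect_equal(itOut$intensity, c(0, 0, 0))
})

test_that("intensity ranks core > middle > periphery across a cohort", {
  packs <- lapply(1:20, function(i)
    packScenario(paste0("C", i), c(100 * i, 0),
                 sigma = runif(1, 3.5, 6)))
  set.seed(202)
  vals <- lapply(packs, function(p) {
    tr <- simulateStationaryTrack(p, 216, seed = 202)
    utilisationIntensity(tr, extractIsopleths(estimateUD(tr)))
  })
  it <- do.call(rbind, vals)
  m <- tapply(it$intensity, it$level, mean)
  expect_gt(m[["0.5"]], m[["0.75"]])
  expect_gt(m[["0.75"]], m[["0.95"]])
  # grid-integration oracle for the circular normal: intensity ratio
  # core/periphery = (50 / (pi R50^2)) / (20 / (pi (R95^2 - R75^2))) per
  # pack, independent of sigma: (50/20) * (ln .05 - ln .25)/ln .5
  oracle <- (50 / 20) * (log(0.05) - log(0.25)) / log(0.5)
  expect_lt(abs(m[["0.5"]] / m[["0.95"]] - oracle) / oracle, 0.30)
})

test_that("overlap-zone occupancy matches geometry limits", {
  farIso <- extractIsopleths(estimateUD(simulateStationaryTrack(
    packScenario("FF", c(400, 400), 4), 300, seed = 4)))
  z0 <- timeInOverlapZone(oracleTrackA, oracleIsoA, farIso)
  expect_equal(z0$proportion_time, 0)
  # a neighbour covering the focal range entirely: occupancy equals the
  # focal pack's own-kernel containment (~0.95)
  bigIso <- extractIsopleths(estimateUD(simulateStationaryTrack(
    packScenario("BIG", c(0, 0), 25), 2000, seed = 9)))
  zc <- timeInOverlapZone(oracleTrackA, oracleIsoA, bigIso)
  own <- fixFractionInIsopleth(oracleTrackA, oracleIsoA, 0.95)
  expect_lt(abs(zc$proportion_time - own), 0.03)
  # co-centred equal packs: both directions approximately equal
  twin <- simulateStationaryTrack(packScenario("TW", c(0, 0), 5), 2000,
                                  seed = 55)
  twinIso <- extractIsopleths(estimateUD(twin))
  za <- timeInOverlapZone(oracleTrackA, oracleIsoA, twinIso)
  zb <- timeInOverlapZone(twin, twinIso, oracleIsoA)
  expect_lt(abs(za$proportion_time - zb$proportion_time), 0.05)
})

test_that("dyadTable builds the long table deterministically", {
  isos <- list(OA = oracleIsoA, OB = oracleIsoB)
  ser <- list(OA = oracleTrackA, OB = oracleTrackB)
  packs <- data.frame(pack_id = c("OA", "OB"), n_adults = c(4, 2),
                      n_yearlings = c(1, 1), n_pups = c(3, 1))
  dy <- data.frame(focal_pack = "OA", neighbour_pack = "OB",
                   relatedness = "related")
  dt <- dyadTable(isos, ser, packs, dy)
  expect_equal(nrow(dt$overlap), 6L)           # 2 directions x 3 levels
  expect_equal(nrow(dt$occupancy), 2L)
  expect_equal(dt$overlap$pack_size_ratio[dt$overlap$focal_pack == "OA"],
               rep(8 / 4, 3))
  # swapping focal/neighbour labels permutes rows, not values
  dySwap <- data.frame(focal_pack = "OB", neighbour_pack = "OA",
                       relatedness = "related")
  dtSwap <- dyadTable(isos, ser, packs, dySwap)
  o1 <- dt$overlap[order(dt$overlap$focal_pack, dt$overlap$level), ]
  o2 <- dtSwap$overlap[order(dtSwap$overlap$focal_pack, dtSwap$overlap$level), ]
  expect_equal(o1$pct_of_focal, o2$pct_of_focal)
  # unknown pack and empty input
  expect_error(dyadTable(isos, ser, packs,
                         data.frame(focal_pack = "OA",
                                    neighbour_pack = "XX",
                                    relatedness = "related")),
               "without fitted isopleths")
  dt0 <- dyadTable(isos, ser, packs, dy[0, ])
  expect_equal(nrow(dt0$overlap), 0L)
  expect_true(all(c("pct_of_focal", "pack_size_ratio") %in%
                    names(dt0$overlap)))
})
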