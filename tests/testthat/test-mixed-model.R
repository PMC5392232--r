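# Profiled-likelihood mixed models, AICc ranking, model averaging and
# prediction curves.

test_that("zero group variance reduces the ML fit to ordinary least squares", {
  d <- simulateOverlapObservations(seed = 12, sigmaB = 0, sigmaE = 8,
                                   beta = c(intercept = 5, related = 10))
  f <- fitLmm(d, c("pack_size_ratio", "relatedness"))
  expect_equal(f$lambda, 0)
  expect_true(f$boundary)
  ols <- lm(pct_overlap_95 ~ pack_size_ratio + relatedness,
            data = transform(d, relatedness = factor(relatedness,
                                                     c("unrelated",
                                                       "related"))))
  expect_equal(unname(f$coefficients), unname(coef(ols)), tolerance = 1e-6)
})

test_that("balanced-case REML variance equals the ANOVA moment estimator", {
  set.seed(4)
  g <- 8L; m <- 5L
  d <- data.frame(focal_pack = rep(paste0("G", 1:g), each = m),
                  relatedness = "unrelated", pack_size_ratio = 1,
                  pct_overlap_95 = rep(rnorm(g, 0, 3), each = m) +
                    rnorm(g * m, 0, 2))
  f <- fitLmm(d, reml = TRUE)
  ybar <- tapply(d$pct_overlap_95, d$focal_pack, mean)
  MSB <- m * var(ybar)
  MSW <- sum((d$pct_overlap_95 -
                ave(d$pct_overlap_95, d$focal_pack))^2) / (g * (m - 1L))
  expect_equal(f$sigma2_b, (MSB - MSW) / m, tolerance = 1e-4)
})

test_that("profiled ML agrees with lme4 and with direct 2-variance search", {
  skip_if_not_installed("lme4")
  d <- simulateOverlapObservations(seed = 21, sigmaB = 5, sigmaE = 8,
                                   beta = c(intercept = 5, ratio = 3,
                                            related = 10))
  termSets <- list(character(),
                   "relatedness",
                   c("pack_size_ratio", "relatedness"),
                   c("pack_size_ratio", "relatedness",
                     "pack_size_ratio:relatedness"))
  forms <- list(pct_overlap_95 ~ 1 + (1 | focal_pack),
                pct_overlap_95 ~ relatedness + (1 | focal_pack),
                pct_overlap_95 ~ pack_size_ratio + relatedness +
                  (1 | focal_pack),
                pct_overlap_95 ~ pack_size_ratio * relatedness +
                  (1 | focal_pack))
  dd <- transform(d, relatedness = factor(relatedness,
                                          c("unrelated", "related")))
  for (i in seq_along(termSets)) {
    f <- fitLmm(d, termSets[[i]])
    m <- lme4::lmer(forms[[i]], data = dd, REML = FALSE)
    expect_equal(f$logLik, as.numeric(stats::logLik(m)), tolerance = 1e-5)
    expect_equal(unname(f$coefficients), unname(lme4::fixef(m)),
                 tolerance = 1e-4)
  }
  # independent route: direct optimisation over both variance components
  for (s in 1:3) {
    ds <- simulateOverlapObservations(seed = 100 + s, nObs = 30,
                                      nGroups = 10)
    f <- fitLmm(ds, "relatedness")
    expect_equal(f$logLik, directMlLogLik(ds, "relatedness"),
                 tolerance = 1e-4)
  }
})

test_that("ML log-likelihood is monotone over nested fixed structures", {
  d <- simulateOverlapObservations(seed = 33)
  ms <- dredgeModels(d)
  ll <- setNames(vapply(ms$fits, function(f) f$logLik, numeric(1)),
                 ms$table$model)
  expect_gte(ll[["ratio"]], ll[["null"]] - 1e-6)
  expect_gte(ll[["ratio+relatedness"]], ll[["relatedness"]] - 1e-6)
  expect_gte(ll[["ratio*relatedness"]], ll[["ratio+relatedness"]] - 1e-6)
})

test_that("the dredge produces five ranked models with unit weight mass", {
  d <- simulateOverlapObservations(seed = 2)
  ms <- dredgeModels(d)
  expect_equal(nrow(ms$table), 5L)
  expect_setequal(ms$table$model,
                  c("null", "ratio", "relatedness", "ratio+relatedness",
                    "ratio*relatedness"))
  expect_equal(sum(ms$table$weight), 1)
  expect_true(all(diff(ms$table$AICc) >= 0))
  expect_true(all(ms$table$AICc > ms$table$AIC))   # finite-N correction
  expect_error(fitLmm(d, "pack_size_ratio:relatedness"), "marginality")
  # AICc blows up when N - k - 1 <= 0
  expect_error(dredgeModels(d[1:6, ]), "AICc undefined")
})

test_that("model averaging follows the hand-computed 3-model fixture", {
  mkFit <- function(coefs, vars) {
    structure(list(coefficients = coefs,
                   vcov = diag(vars, length(vars)) |>
                     `dimnames<-`(list(names(coefs), names(coefs)))),
              class = "lmmFit")
  }
  fits <- list(
    A = mkFit(c(`(Intercept)` = 2, x = 1), c(0.4, 0.09)),
    B = mkFit(c(`(Intercept)` = 3), c(0.25)),
    C = mkFit(c(`(Intercept)` = 1, x = 2), c(0.16, 0.04)))
  ms <- structure(list(
    fits = fits,
    table = data.frame(model = c("A", "B", "C"), weight = c(0.5, 0.3, 0.2)),
    data = data.frame(pack_size_ratio = c(0.5, 2))), class = "modelSet")
  avg <- modelAverage(ms, cumWeight = 0.95)
  tab <- avg$table
  xr <- tab[tab$parameter == "x", ]
  # full average with zero substitution: 0.5*1 + 0.3*0 + 0.2*2 = 0.9
  expect_equal(xr$estimate, 0.9)
  # unconditional SE: sqrt(sum w (var + (b - bbar)^2))
  expect_equal(xr$se, sqrt(0.5 * (0.09 + 0.01) + 0.3 * (0 + 0.81) +
                             0.2 * (0.04 + 1.21)))
  # importance: weight mass of the models containing x
  expect_equal(xr$importance, 0.7)
  expect_equal(tab$importance[tab$parameter == "(Intercept)"], 1)
  # conditional average renormalises over A and C only
  expect_equal(xr$estimate_cond, (0.5 * 1 + 0.2 * 2) / 0.7)
  # degenerate case: one model holding (almost) all the weight
  ms1 <- ms; ms1$table$weight <- c(0.99, 0.007, 0.003)
  avg1 <- modelAverage(ms1, cumWeight = 0.95)
  expect_equal(avg1$selected, "A")
  expect_equal(avg1$table$estimate,
               unname(fits$A$coefficients[avg1$table$parameter]))
})

test_that("averaged predictions reduce to the weighted per-model means", {
  d <- simulateOverlapObservations(seed = 44, beta = c(intercept = 5,
                                                       ratio = 2,
                                                       related = 8))
  ms <- dredgeModels(d)
  avg <- modelAverage(ms)
  relNum <- mean(d$relatedness == "related")
  xbar <- c(`(Intercept)` = 1, pack_size_ratio = mean(d$pack_size_ratio),
            relatednessrelated = relNum,
            `pack_size_ratio:relatednessrelated` =
              mean(d$pack_size_ratio * (d$relatedness == "related")))
  predAvg <- sum(xbar[avg$table$parameter] * avg$table$estimate)
  perModel <- vapply(seq_along(avg$selected), function(i) {
    b <- ms$fits[[i]]$coefficients
    sum(xbar[names(b)] * b)
  }, numeric(1))
  expect_equal(predAvg, sum(avg$weights * perModel), tolerance = 1e-10)
})

test_that("interaction surfaces recover the generating geometry", {
  # zero slope and interaction: two horizontal lines split by relatedness
  mkFit <- function(coefs, vars)
    structure(list(coefficients = coefs,
                   vcov = diag(vars, length(vars)) |>
                     `dimnames<-`(list(names(coefs), names(coefs)))),
              class = "lmmFit")
  ms <- structure(list(
    fits = list(M = mkFit(c(`(Intercept)` = 4, relatednessrelated = 9),
                          c(1, 1))),
    table = data.frame(model = "M", weight = 1),
    data = data.frame(pack_size_ratio = c(0.5, 2))), class = "modelSet")
  ps <- predictInteractionSurface(modelAverage(ms))
  expect_equal(unique(ps$predicted[ps$relatedness == "unrelated"]), 4)
  expect_equal(unique(ps$predicted[ps$relatedness == "related"]), 13)
  expect_warning(predictInteractionSurface(modelAverage(ms),
                                           ratioGrid = c(0.1, 3)),
                 "beyond the observed")
  # ratio slope only among unrelated dyads: recovered in most replicates
  hits <- 0L
  for (s in 1:60) {
    d <- simulateOverlapObservations(
      seed = 400 + s, beta = c(intercept = 3, ratio = 8, related = 12,
                               interaction = -8),
      sigmaB = 3, sigmaE = 5)
    avg <- modelAverage(dredgeModels(d))
    ps <- suppressWarnings(
      predictInteractionSurface(avg, ratioGrid = c(1, 2)))
    slope <- function(lev) diff(ps$predicted[ps$relatedness == lev])
    if (slope("unrelated") > 0 && abs(slope("related")) <
          slope("unrelated")) hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.8)
})
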