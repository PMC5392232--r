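# Random-intercept linear mixed models for directional overlap, fitted by
# maximum likelihood with the variance ratio profiled out, plus the AICc
# multimodel machinery: the marginality-respecting model set, Akaike
# weights, cumulative-weight model averaging and prediction curves.
#
# Model: y = X beta + Z b + e, b ~ N(0, sigma_b^2 I) over focal packs,
# e ~ N(0, sigma_e^2 I). For a fixed ratio lambda = sigma_b^2 / sigma_e^2
# the GLS estimate and the ML residual variance are closed-form, leaving a
# 1-D profiled log-likelihood optimised over lambda >= 0.

.canonicalTerms <- c("pack_size_ratio", "relatedness",
                     "pack_size_ratio:relatedness")

.designMatrix <- function(data, terms) {
  data$relatedness <- factor(data$relatedness,
                             levels = c("unrelated", "related"))
  f <- stats::reformulate(if (length(terms)) terms else "1")
  stats::model.matrix(f, data)
}

.profileLogLik <- function(lambda, X, y, ZZt, reml = FALSE) {
  n <- length(y)
  p <- ncol(X)
  R <- chol(diag(n) + lambda * ZZt)
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  qrx <- qr(Xw)
  if (qrx$rank < p) stop("singular design matrix")
  beta <- qr.coef(qrx, yw)
  names(beta) <- colnames(X)
  res <- yw - Xw %*% beta
  rss <- sum(res^2)
  logdetS <- 2 * sum(log(diag(R)))
  XtX <- crossprod(Xw)
  if (reml) {
    s2e <- rss / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi) + log(s2e) + 1) + logdetS +
                    determinant(XtX, logarithm = TRUE)$modulus[1])
  } else {
    s2e <- rss / n
    ll <- -0.5 * (n * (log(2 * pi) + log(s2e) + 1) + logdetS)
  }
  list(ll = ll, beta = drop(beta), s2e = s2e, XtX = XtX)
}

#' Fit a random-intercept linear mixed model by profiled ML
#'
#' Fits `response ~ fixed terms + (1 | group)` by maximum likelihood (not
#' REML, so that information criteria are comparable across fixed-effect
#' structures). The profiled log-likelihood over the variance ratio
#' `lambda = sigma_b^2 / sigma_e^2` is maximised on `[0, 1e4]` via a
#' log-spaced grid refined by golden-section search; `lambda = 0` (no
#' group variance) is always evaluated, so the fit reduces exactly to
#' ordinary least squares at the boundary.
#'
#' @param data data.frame with the response, covariates and grouping column.
#' @param terms character vector of fixed-effect terms from
#'   `pack_size_ratio`, `relatedness`, `pack_size_ratio:relatedness`
#'   (the intercept is always included; empty vector fits the null model).
#' @param response,group column names of the response and grouping factor.
#' @param lambdaMax upper search bound for the variance ratio.
#' @param reml use restricted maximum likelihood instead of ML. REML gives
#'   less biased variance components (and reduces to the ANOVA
#'   method-of-moments estimator in the balanced one-way case) but its
#'   likelihoods are not comparable across fixed-effect structures, so all
#'   information-criterion work uses ML; REML is a refit option for
#'   reporting final variance components only.
#' @return object of class `lmmFit`: coefficients, `vcov`, `sigma2_b`,
#'   `sigma2_e`, `lambda`, `logLik`, `k` (fixed coefficients + 2 variance
#'   components), `N`, `nGroups`, `boundary` flag and the term set.
#' @export
fitLmm <- function(data, terms = character(),
                   response = "pct_overlap_95", group = "focal_pack",
                   lambdaMax = 1e4, reml = FALSE) {
  y <- data[[response]]
  if (is.null(y) || anyNA(y) || any(!is.finite(y)))
    stop("response must be present and finite")
  bad <- setdiff(terms, .canonicalTerms)
  if (length(bad)) stop("unknown terms: ", paste(bad, collapse = ", "))
  if ("pack_size_ratio:relatedness" %in% terms &&
      !all(c("pack_size_ratio", "relatedness") %in% terms))
    stop("interaction requires both main effects (marginality)")
  gfac <- factor(data[[group]])
  if (nlevels(gfac) < 2L) stop("need at least 2 grouping levels")
  X <- .designMatrix(data, terms)
  Z <- stats::model.matrix(~ gfac - 1)
  ZZt <- tcrossprod(Z)
  obj <- function(lam) .profileLogLik(lam, X, y, ZZt, reml = reml)$ll
  grid <- c(0, 10^seq(-6, log10(lambdaMax), length.out = 60))
  lls <- vapply(grid, obj, numeric(1))
  best <- which.max(lls)
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  lambda <- grid[best]
  if (hi > lo) {
    opt <- stats::optimize(obj, interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-10)
    if (opt$objective > lls[best]) lambda <- opt$maximum
  }
  fit <- .profileLogLik(lambda, X, y, ZZt, reml = reml)
  p <- ncol(X)
  vc <- fit$s2e * solve(fit$XtX)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(terms = terms, coefficients = fit$beta, vcov = vc,
                 sigma2_e = fit$s2e, sigma2_b = lambda * fit$s2e,
                 lambda = lambda, logLik = fit$ll, k = p + 2L,
                 N = length(y), nGroups = nlevels(gfac),
                 boundary = lambda <= 0 || lambda >= 0.99 * lambdaMax,
                 reml = reml, response = response, group = group),
            class = "lmmFit")
}

#' @export
print.lmmFit <- function(x, ...) {
  cat("Linear mixed model (ML, random intercept by ", x$group, ")\n",
      sep = "")
  cat("  fixed: ", if (length(x$terms))
    paste(x$terms, collapse = " + ") else "(intercept only)", "\n", sep = "")
  cat(sprintf("  logLik = %.4f, sigma_b = %.3f, sigma_e = %.3f%s\n",
              x$logLik, sqrt(x$sigma2_b), sqrt(x$sigma2_e),
              if (x$boundary) " (boundary fit)" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

.aicc <- function(logLik, k, N) {
  if (N - k - 1 <= 0)
    stop("AICc undefined: N - k - 1 <= 0 (N = ", N, ", k = ", k, ")")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (N - k - 1)
}

#' Fit the marginality-respecting candidate model set
#'
#' Generates all subsets of the fixed terms that respect marginality (the
#' interaction only appears with both main effects): null, ratio only,
#' relatedness only, both mains, and both mains plus interaction — five
#' models. Each is fitted by [fitLmm()] and ranked by AICc with Akaike
#' weights.
#'
#' @inheritParams fitLmm
#' @return object of class `modelSet`: `fits` (list of `lmmFit` in AICc
#'   order), `table` (model, k, logLik, AIC, AICc, delta, weight), and the
#'   data used.
#' @export
dredgeModels <- function(data, response = "pct_overlap_95",
                         group = "focal_pack") {
  specs <- list(
    "null" = character(),
    "ratio" = "pack_size_ratio",
    "relatedness" = "relatedness",
    "ratio+relatedness" = c("pack_size_ratio", "relatedness"),
    "ratio*relatedness" = c("pack_size_ratio", "relatedness",
                            "pack_size_ratio:relatedness"))
  fits <- lapply(specs, function(tr)
    fitLmm(data, terms = tr, response = response, group = group))
  aicc <- vapply(fits, function(f) .aicc(f$logLik, f$k, f$N), numeric(1))
  aic <- vapply(fits, function(f) -2 * f$logLik + 2 * f$k, numeric(1))
  ord <- order(aicc)
  fits <- fits[ord]; aicc <- aicc[ord]; aic <- aic[ord]
  delta <- aicc - aicc[1]
  w <- exp(-delta / 2); w <- w / sum(w)
  tab <- data.frame(
    model = names(fits),
    k = vapply(fits, function(f) f$k, integer(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    AIC = aic, AICc = aicc, delta = delta, weight = w,
    row.names = NULL)
  structure(list(fits = fits, table = tab, data = data,
                 response = response, group = group),
            class = "modelSet")
}

#' @export
print.modelSet <- function(x, ...) {
  cat("Candidate mixed models ranked by AICc",
      " (k = fixed coefficients + 2 variance components)\n", sep = "")
  tab <- x$table
  tab$logLik <- round(tab$logLik, 2); tab$AIC <- round(tab$AIC, 2)
  tab$AICc <- round(tab$AICc, 2); tab$delta <- round(tab$delta, 2)
  tab$weight <- round(tab$weight, 3)
  print(tab)
  invisible(x)
}

#' Model-averaged coefficients over the cumulative-weight top set
#'
#' Retains the smallest prefix of the AICc ranking whose cumulative Akaike
#' weight exceeds `cumWeight`, renormalises the weights, and forms
#' full-average (zero-substitution) estimates: a model not containing a
#' term contributes a zero coefficient with zero variance. Unconditional
#' standard errors follow the revised multimodel formula
#' `sqrt(sum w_i (var_i + (b_i - bbar)^2))`; 95% intervals use the normal
#' 1.96 multiplier and p-values a Wald z reference. Relative importance of
#' a term is the renormalised weight mass of the selected models that
#' contain it. Conditional (natural) averages over only the models
#' containing each term are reported alongside.
#'
#' @param modelSet a [dredgeModels()] result.
#' @param cumWeight cumulative-weight threshold for the selected top set.
#' @return object of class `averagedModel` with a coefficient `table`
#'   (estimate, se, ci_lower, ci_upper, p, importance, conditional
#'   estimate/se), the selected model names and renormalised weights, and
#'   the observed covariate range for prediction.
#' @export
modelAverage <- function(modelSet, cumWeight = 0.95) {
  stopifnot(inherits(modelSet, "modelSet"))
  tab <- modelSet$table
  if (nrow(tab) == 0L) stop("empty model set")
  nSel <- which(cumsum(tab$weight) > cumWeight)[1]
  if (is.na(nSel)) nSel <- nrow(tab)
  sel <- seq_len(nSel)
  w <- tab$weight[sel] / sum(tab$weight[sel])
  fits <- modelSet$fits[sel]
  coefNames <- unique(unlist(lapply(fits, function(f) names(f$coefficients))))
  rows <- lapply(coefNames, function(cn) {
    est <- var <- has <- numeric(length(fits))
    for (i in seq_along(fits)) {
      b <- fits[[i]]$coefficients
      if (cn %in% names(b)) {
        est[i] <- b[[cn]]
        var[i] <- fits[[i]]$vcov[cn, cn]
        has[i] <- 1
      }
    }
    full <- sum(w * est)
    seFull <- sqrt(sum(w * (var + (est - full)^2)))
    wc <- w[has == 1] / sum(w[has == 1])
    cond <- sum(wc * est[has == 1])
    seCond <- sqrt(sum(wc * (var[has == 1] + (est[has == 1] - cond)^2)))
    z <- full / seFull
    data.frame(parameter = cn, estimate = full, se = seFull,
               ci_lower = full - 1.96 * seFull,
               ci_upper = full + 1.96 * seFull,
               p = 2 * stats::pnorm(-abs(z)),
               importance = sum(w[has == 1]),
               estimate_cond = cond, se_cond = seCond)
  })
  ratios <- modelSet$data$pack_size_ratio
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 selected = tab$model[sel], weights = w,
                 cumWeight = cumWeight,
                 ratioRange = if (!is.null(ratios)) range(ratios) else c(NA, NA)),
            class = "averagedModel")
}

#' @export
print.averagedModel <- function(x, ...) {
  cat("Model-averaged effects (full averaging over ",
      length(x$selected), " models, cumulative weight > ",
      x$cumWeight, ")\n", sep = "")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, 4)
  print(tab)
  invisible(x)
}

#' Predicted overlap over the observed pack-size-ratio range
#'
#' Evaluates the model-averaged linear predictor on a grid of pack-size
#' ratios for each relatedness level — the prediction curves behind the
#' interaction plot. Predictions below zero are additionally reported
#' clamped at zero, since percent overlap cannot be negative.
#'
#' @param avg an [modelAverage()] result.
#' @param ratioGrid numeric grid of ratios; defaults to 50 points spanning
#'   the observed range. Values outside the observed range trigger a
#'   warning (extrapolation), not an error.
#' @param relatednessLevels levels to predict for.
#' @return data.frame: `pack_size_ratio`, `relatedness`, `predicted`,
#'   `predicted_clamped`.
#' @export
predictInteractionSurface <- function(avg, ratioGrid = NULL,
                                      relatednessLevels = c("unrelated",
                                                            "related")) {
  stopifnot(inherits(avg, "averagedModel"))
  rr <- avg$ratioRange
  if (is.null(ratioGrid))
    ratioGrid <- seq(rr[1], rr[2], length.out = 50)
  if (!anyNA(rr) && (min(ratioGrid) < rr[1] - 1e-9 ||
                     max(ratioGrid) > rr[2] + 1e-9))
    warning("ratio grid extends beyond the observed data range")
  b <- stats::setNames(avg$table$estimate, avg$table$parameter)
  coef0 <- function(nm) if (nm %in% names(b)) b[[nm]] else 0
  rows <- lapply(relatednessLevels, function(lev) {
    rel <- as.numeric(lev == "related")
    pred <- coef0("(Intercept)") + coef0("pack_size_ratio") * ratioGrid +
      coef0("relatednessrelated") * rel +
      coef0("pack_size_ratio:relatednessrelated") * ratioGrid * rel
    data.frame(pack_size_ratio = ratioGrid, relatedness = lev,
               predicted = pred, predicted_clamped = pmax(0, pred))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Simulate directional-overlap observations for model validation
#'
#' Draws a dataset with the structure of the dyad-level analysis: `nObs`
#' directional observations distributed over `nGroups` focal packs, a
#' related/unrelated label, a positive pack-size ratio, and a Gaussian
#' response built from known fixed effects, a random intercept per focal
#' pack and residual noise. Used for parameter-recovery and
#' model-selection checks.
#'
#' @param nObs,nGroups observations and focal-pack groups.
#' @param beta named fixed effects: `intercept`, `ratio`, `related`,
#'   `interaction` (any subset; missing entries are zero).
#' @param sigmaB,sigmaE random-intercept and residual SDs.
#' @param propRelated proportion of observations labelled related.
#' @param seed integer seed.
#' @return data.frame with `focal_pack`, `relatedness`, `pack_size_ratio`,
#'   `pct_overlap_95`.
#' @export
simulateOverlapObservations <- function(nObs = 40, nGroups = 19,
                                        beta = c(intercept = 5, ratio = 0,
                                                 related = 10,
                                                 interaction = 0),
                                        sigmaB = 5, sigmaE = 8,
                                        propRelated = 0.6, seed = 1L) {
  set.seed(seed)
  b <- function(nm) if (nm %in% names(beta)) beta[[nm]] else 0
  grp <- sort(rep_len(seq_len(nGroups), nObs))
  rel <- rep("unrelated", nObs)
  rel[sample.int(nObs, round(propRelated * nObs))] <- "related"
  ratio <- exp(stats::rnorm(nObs, 0, 0.4))
  u <- stats::rnorm(nGroups, 0, sigmaB)
  relNum <- as.numeric(rel == "related")
  y <- b("intercept") + b("ratio") * ratio + b("related") * relNum +
    b("interaction") * ratio * relNum + u[grp] +
    stats::rnorm(nObs, 0, sigmaE)
  data.frame(focal_pack = paste0("P", grp), relatedness = rel,
             pack_size_ratio = ratio, pct_overlap_95 = y)
}
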