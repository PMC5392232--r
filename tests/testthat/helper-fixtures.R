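# Shared fixtures, built once per test run. Heavy objects (long tracks and
# their kernel surfaces) are reused across test files to keep the suite fast.

# Two equal-sigma OU packs 10 km apart, 2000 fixes each: the canonical
# oracle pair for overlap and containment checks.
oraclePackA <- packScenario("OA", center = c(0, 0), sigma = 5, tau = 24)
oraclePackB <- packScenario("OB", center = c(10, 0), sigma = 5, tau = 24)
oracleTrackA <- simulateStationaryTrack(oraclePackA, 2000, seed = 101L)
oracleTrackB <- simulateStationaryTrack(oraclePackB, 2000, seed = 101L)
oracleUdA <- estimateUD(oracleTrackA)
oracleUdB <- estimateUD(oracleTrackB)
oracleIsoA <- extractIsopleths(oracleUdA)
oracleIsoB <- extractIsopleths(oracleUdB)

# A hand-built uniform UD: unit mass spread over an exact block of cells,
# for deterministic isopleth tie-break checks.
uniformUD <- function(nCells = 100L, nx = 10L, cell = 100) {
  ny <- ceiling(nCells / nx)
  d <- matrix(0, nx, ny)
  d[seq_len(nCells)] <- 1 / (nCells * cell^2)
  new("UtilizationDistribution", packId = "U", origin = c(0, 0),
      cellSize = cell, density = d, bandwidth = c(1, 1),
      nFixes = 1L)
}

# Fix table at regular intervals for subsampling tests.
hourlyFixes <- function(days, hours = 0:23, start = as.Date("2023-10-01")) {
  ts <- as.POSIXct(paste(rep(start + seq_len(days) - 1L, each = length(hours)),
                         sprintf("%02d:00:00", hours)), tz = "UTC")
  data.frame(timestamp = ts, x = seq_along(ts) * 10, y = rev(seq_along(ts)) * 10)
}

# Independent brute-force two-sided Mann-Whitney p: enumerate all value
# labellings and compute U by direct pairwise comparison counting (a route
# distinct from the package's rank-sum + enumeration path).
bruteForceMwuP <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  uOf <- function(av, bv)
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  uObs <- uOf(a, b)
  mu <- n1 * length(b) / 2
  combos <- utils::combn(length(pooled), n1)
  uAll <- apply(combos, 2, function(ix) uOf(pooled[ix], pooled[-ix]))
  mean(abs(uAll - mu) >= abs(uObs - mu) - 1e-9)
}

# Direct 2-variance-parameter ML log-likelihood maximiser (independent of
# the package's profiled search): optimises over (log sigma_b, log sigma_e)
# with the exact Gaussian likelihood, concentrating nothing.
directMlLogLik <- function(data, terms, response = "pct_overlap_95",
                           group = "focal_pack") {
  data$relatedness <- factor(data$relatedness, c("unrelated", "related"))
  f <- stats::reformulate(if (length(terms)) terms else "1")
  X <- stats::model.matrix(f, data)
  y <- data[[response]]
  Z <- stats::model.matrix(~ factor(data[[group]]) - 1)
  ZZt <- tcrossprod(Z)
  n <- length(y)
  negll <- function(par) {
    s2b <- exp(2 * par[1]); s2e <- exp(2 * par[2])
    V <- s2e * diag(n) + s2b * ZZt
    R <- chol(V)
    beta <- qr.coef(qr(backsolve(R, X, transpose = TRUE)),
                    backsolve(R, y, transpose = TRUE))
    r <- backsolve(R, y - X %*% beta, transpose = TRUE)
    0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(r^2))
  }
  best <- Inf
  for (s in list(c(0, 1), c(1, 1), c(-2, 0.5))) {
    o <- stats::optim(s, negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  -best
}
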