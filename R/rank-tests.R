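# Rank-based comparisons used in the overlap analysis: Mann-Whitney U with
# exact small-sample enumeration, tie-corrected Kruskal-Wallis, and
# Tukey-type (Nemenyi) all-pairs comparisons on mean ranks.

#' Descriptive summary in the reporting format n / mean / median / SD / range
#'
#' @param values non-empty numeric vector.
#' @return one-row data.frame: `n`, `mean`, `median`, `sd` (denominator
#'   n - 1; `NA` for a single value), `min`, `max`.
#' @examples
#' summarizeValues(c(2, 4, 6))
#' @export
summarizeValues <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) stop("values must be non-empty and finite")
  data.frame(n = length(values), mean = mean(values),
             median = stats::median(values),
             sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
             min = min(values), max = max(values))
}

# Exact two-sided Mann-Whitney p: enumerate all C(n1+n2, n1) assignments of
# the pooled midranks to the first group and take the symmetric tail
# P(|U - n1 n2 / 2| >= |U_obs - n1 n2 / 2|).
.mwuExactP <- function(pooledRanks, n1, Uobs) {
  N <- length(pooledRanks)
  mu <- n1 * (N - n1) / 2
  offset <- n1 * (n1 + 1) / 2
  combos <- utils::combn(N, n1)
  rs <- colSums(matrix(pooledRanks[combos], nrow = n1))
  Uall <- rs - offset
  mean(abs(Uall - mu) >= abs(Uobs - mu) - 1e-9)
}

#' Mann-Whitney rank-sum test
#'
#' U is computed from midranks of the pooled sample (U of the first group:
#' rank sum minus `n1 (n1 + 1) / 2`); T is the rank sum of the smaller
#' group (first group on a size tie). The two-sided p-value is exact — full
#' enumeration over group labellings, valid under ties — when
#' `n1 * n2 <= 20`, and otherwise uses the normal approximation with tie
#' correction and a 0.5 continuity correction.
#'
#' @param a,b numeric samples (the first group is the reference for U).
#' @param exactMax use exact enumeration when `n1 * n2` does not exceed this.
#' @return object of class `rankTest`: list with `method`, `U`, `T`,
#'   `p_value`, `n1`, `n2`, `exact`, `tie_corrected`.
#' @examples
#' mannWhitney(c(1, 2), c(3, 4))
#' @export
mannWhitney <- function(a, b, exactMax = 20) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) stop("both groups need at least one value")
  if (anyNA(c(a, b)) || any(!is.finite(c(a, b)))) stop("values must be finite")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))              # midranks
  Ra <- sum(r[seq_len(n1)])
  U <- Ra - n1 * (n1 + 1) / 2
  Tsmall <- if (n1 <= n2) Ra else sum(r[n1 + seq_len(n2)])
  ties <- table(r)
  tieSum <- sum(ties^3 - ties)
  hasTies <- any(ties > 1)
  exact <- n1 * n2 <= exactMax
  if (exact) {
    p <- .mwuExactP(r, n1, U)
  } else {
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tieSum / (N * (N - 1)))
    z <- (abs(U - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- min(1, 2 * stats::pnorm(-z))
  }
  structure(list(method = "Mann-Whitney Rank Sum Test", U = U, T = Tsmall,
                 p_value = p, n1 = n1, n2 = n2, exact = exact,
                 tie_corrected = !exact && hasTies),
            class = "rankTest")
}

#' Kruskal-Wallis test (analysis of variance on ranks)
#'
#' Tie-corrected H statistic compared against a chi-square reference with
#' k - 1 degrees of freedom.
#'
#' @param groups list of numeric vectors (at least two, each non-empty).
#' @return object of class `rankTest`: list with `method`, `H`, `df`,
#'   `p_value`, `n`, `tie_corrected`.
#' @export
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups")
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("every group must contain at least one value")
  x <- unlist(groups, use.names = FALSE)
  if (anyNA(x) || any(!is.finite(x))) stop("values must be finite")
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (N + 1)
  ties <- table(r)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C > 0) H <- H / C
  df <- length(groups) - 1L
  structure(list(method = "Kruskal-Wallis ANOVA on ranks", H = H, df = df,
                 p_value = stats::pchisq(H, df, lower.tail = FALSE),
                 n = vapply(groups, length, integer(1)),
                 tie_corrected = any(ties > 1)),
            class = "rankTest")
}

#' Tukey-type all-pairs comparisons on mean ranks (Nemenyi)
#'
#' Follow-up to [kruskalWallis()]: for every pair of groups the difference
#' in mean ranks is standardised by the (tie-corrected) pooled rank
#' variance and referred to the studentized-range distribution with k
#' groups and infinite degrees of freedom. All comparisons are two-sided at
#' a common alpha; no step-down refinement.
#'
#' @param groups list of at least two named or unnamed numeric vectors.
#' @param alpha family significance level for the `significant` flag.
#' @return data.frame with one row per pair: `group_i`, `group_j`,
#'   `mean_rank_i`, `mean_rank_j`, `q` (studentized-range scale statistic),
#'   `p_adj`, `significant`.
#' @export
pairwiseTukeyOnRanks <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups")
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("every group must contain at least one value")
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), vapply(groups, length, integer(1)))
  N <- length(x)
  r <- rank(x)
  mr <- tapply(r, g, mean)
  n <- tabulate(g)
  ties <- table(r)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  v <- N * (N + 1) / 12 * C
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    se <- sqrt(v * (1 / n[i] + 1 / n[j]))
    q <- abs(mr[i] - mr[j]) / se * sqrt(2)
    p <- stats::ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      group_i = nm[i], group_j = nm[j],
      mean_rank_i = unname(mr[i]), mean_rank_j = unname(mr[j]),
      q = unname(q), p_adj = unname(p), significant = unname(p < alpha))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.rankTest <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$U))
    cat(sprintf("U = %.1f; T = %.1f; P = %s%s\n", x$U, x$T,
                format.pval(x$p_value, digits = 3),
                if (x$exact) " (exact)" else ""))
  if (!is.null(x$H))
    cat(sprintf("H = %.1f, df = %d, P = %s\n", x$H, x$df,
                format.pval(x$p_value, digits = 3)))
  invisible(x)
}
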