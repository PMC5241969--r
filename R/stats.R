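# Shared statistical machinery: the odds-ratio / enrichment Z machinery, the
# upper-tail cumulative binomial test and a Mann-Whitney U test with both a
# tie-corrected normal approximation and an exact permutation route.

#' Upper-tail cumulative binomial p value
#'
#' P(X >= k) for X ~ Binomial(n, p0); the concordance test used to compare a
#' focal pair category against a reference category.
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null success probability.
#' @return the exact upper-tail probability.
#' @export
binom_upper_p <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 >= 0, p0 <= 1)
  if (k == 0) return(1)
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Odds ratio with log-scale standard error
#'
#' OR = (p1/(1-p1)) / (p2/(1-p2)) where p1 = k1/n1 and p2 = k2/n2, with
#' SE(ln OR) = sqrt(1/k1 + 1/(n1-k1) + 1/k2 + 1/(n2-k2)). All four SE
#' denominators must be positive; no continuity correction is applied.
#'
#' @param k1,n1 "region" count and total in the first margin (mutations).
#' @param k2,n2 "region" count and total in the second margin (residues).
#' @return an [enrichment_result()].
#' @export
odds_ratio_test <- function(k1, n1, k2, n2) {
  cells <- c(k1, n1 - k1, k2, n2 - k2)
  if (any(cells <= 0)) {
    stop("odds-ratio SE undefined: a count cell is zero (",
         paste(cells, collapse = ", "),
         "); no automatic continuity correction is applied")
  }
  p1 <- k1 / n1; p2 <- k2 / n2
  or <- (p1 / (1 - p1)) / (p2 / (1 - p2))
  se <- sqrt(sum(1 / cells))
  enrichment_result(or, se)
}

#' Length-normalised enrichment with log-scale standard error
#'
#' Enrichment = (k * L) / (n * l) for k of n events landing in a region of
#' length l out of total length L, with
#' SE(ln E) = sqrt(1/k - 1/n + 1/l - 1/L). When k = 0 the estimate is 0, the
#' SE undefined, and the result flagged.
#'
#' @param k events in the region.
#' @param n total events.
#' @param l region length.
#' @param L total length.
#' @return an [enrichment_result()].
#' @export
log_enrichment_test <- function(k, n, l, L) {
  stopifnot(n > 0, l > 0, L > 0)
  if (k == 0) {
    return(enrichment_result(0, NA_real_, flagged = TRUE))
  }
  est <- (k * L) / (n * l)
  se <- sqrt(1 / k - 1 / n + 1 / l - 1 / L)
  enrichment_result(est, se)
}

rank_sum_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided test that two samples come from the same distribution. Reports
#' the U statistic of the first sample, a normal-approximation p value with
#' tie correction (no continuity correction, so identical groups give p = 1),
#' and -- when n1 + n2 <= `exact_max` -- an exact permutation p value obtained
#' by enumerating all group labelings.
#'
#' @param x,y numeric samples.
#' @param exact_max largest combined sample size for which the exact
#'   enumeration is computed (default 12).
#' @return list with `U`, `p` (the exact value when available, otherwise the
#'   approximation), `p_approx`, `p_exact` (NA when not enumerated), and the
#'   group means and medians.
#' @export
mann_whitney <- function(x, y, exact_max = 12) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  U <- rank_sum_u(x, y)
  N <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    p_approx <- 1
  } else {
    z <- (U - mu) / sqrt(sigma2)
    p_approx <- min(1, 2 * pnorm(-abs(z)))
  }
  p_exact <- NA_real_
  if (N <= exact_max) {
    pool <- c(x, y)
    dev_obs <- abs(U - mu)
    combos <- combn(N, n1)
    devs <- apply(combos, 2, function(idx)
      abs(rank_sum_u(pool[idx], pool[-idx]) - mu))
    p_exact <- mean(devs >= dev_obs - 1e-12)
  }
  list(U = U,
       p = if (!is.na(p_exact)) p_exact else p_approx,
       p_approx = p_approx, p_exact = p_exact,
       mean_x = mean(x), mean_y = mean(y),
       median_x = median(x), median_y = median(y),
       n1 = n1, n2 = n2)
}

#' Standard error of a proportion
#' @param f observed fraction.
#' @param n sample size.
#' @keywords internal
prop_sem <- function(f, n) sqrt(f * (1 - f) / n)

# Seeded evaluation: run expr with a temporary RNG state derived from `seed`,
# restoring the caller's stream afterwards. All generator determinism flows
# through this.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
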