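#' Kendall partial rank correlation
#'
#' Tie-adjusted (tau-b) Kendall correlation between `x` and `y`,
#' optionally partialled on covariates: with covariates, the partial tau
#' comes from the inverse of the pairwise tau-b correlation matrix of
#' (x, y, covariates), the standard higher-order recursion. The two-sided
#' p-value uses the normal approximation
#' z = 3 tau sqrt(m (m - 1)) / sqrt(2 (2 m + 5)) with m = n - (number of
#' covariates), matching common partial-correlation practice.
#'
#' @param x,y Numeric vectors of equal length (>= 4).
#' @param covariates Optional list (or single vector / matrix columns) of
#'   numeric covariates to control for.
#' @return List with tau, p, n, and the covariate count.
#' @export
kendall_partial <- function(x, y, covariates = NULL) {
  if (length(x) != length(y) || length(x) < 4) {
    stop("`x` and `y` must have equal length >= 4")
  }
  covs <- if (is.null(covariates)) {
    list()
  } else if (is.list(covariates)) {
    covariates
  } else if (is.matrix(covariates)) {
    lapply(seq_len(ncol(covariates)), function(j) covariates[, j])
  } else {
    list(covariates)
  }
  vars <- c(list(x, y), covs)
  if (any(vapply(vars, function(v) stats::sd(v) == 0, TRUE))) {
    stop("constant vector: Kendall correlation undefined")
  }
  q <- length(covs)
  if (q == 0) {
    tau <- stats::cor(x, y, method = "kendall")
  } else {
    M <- do.call(cbind, vars)
    R <- stats::cor(M, method = "kendall")
    Ri <- solve(R)
    tau <- -Ri[1, 2] / sqrt(Ri[1, 1] * Ri[2, 2])
  }
  m <- length(x) - q
  z <- 3 * tau * sqrt(m * (m - 1)) / sqrt(2 * (2 * m + 5))
  p <- 2 * stats::pnorm(-abs(z))
  list(tau = tau, p = p, n = length(x), n_covariates = q)
}

#' One- and two-sample z-tests for proportions
#'
#' One-sample: z = (k1/n1 - p0) / sqrt(p0 (1 - p0) / n1). Two-sample:
#' pooled-variance z for the difference of proportions. Both two-sided,
#' without continuity correction.
#'
#' @param k1,n1 Successes and trials of the first sample.
#' @param k2 Either the second sample's successes, or (when `n2` is
#'   missing) the null proportion `p0` may be given instead.
#' @param n2 Trials of the second sample (two-sample test when present).
#' @param p0 Null proportion for the one-sample test (default 0.5).
#' @return List with z and two-sided p.
#' @export
prop_ztest <- function(k1, n1, k2 = NULL, n2 = NULL, p0 = 0.5) {
  if (n1 <= 0) stop("`n1` must be positive")
  if (k1 > n1) stop("successes cannot exceed trials")
  if (is.null(n2)) {
    if (!is.null(k2)) p0 <- k2
    if (p0 <= 0 || p0 >= 1) stop("`p0` must lie in (0, 1)")
    z <- (k1 / n1 - p0) / sqrt(p0 * (1 - p0) / n1)
  } else {
    if (n2 <= 0) stop("`n2` must be positive")
    if (k2 > n2) stop("successes cannot exceed trials")
    p_pool <- (k1 + k2) / (n1 + n2)
    denom <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
    if (denom == 0) return(list(z = 0, p = 1))
    z <- (k1 / n1 - k2 / n2) / denom
  }
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples: exact enumeration p-value when the
#' smaller sample has at most 8 observations and there are no ties,
#' otherwise the tie-corrected normal approximation. U counts pairs where
#' an `a` observation precedes a `b` observation (ties half).
#'
#' @param a,b Non-empty numeric samples.
#' @return List with U, two-sided p, and the method used.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (min(n1, n2) <= 8 && !ties) {
    p <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tab <- table(r)
    tie_term <- sum(tab^3 - tab) / ((n1 + n2) * (n1 + n2 - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term))
    z <- (u - mu - 0.5 * sign(u - mu)) / sigma   # continuity-corrected
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = u, p = p, method = method)
}
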