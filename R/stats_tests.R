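new_test_result <- function(method, statistic, p_value, n) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(method = method, statistic = unname(statistic),
                 p_value = min(unname(p_value), 1), n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, two-sided P = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact null by enumeration of all group assignments when the pooled sample
#' size is at most `exact_max` (default 20); tie-corrected normal
#' approximation with continuity correction above that. The statistic is `U` for the first sample
#' (number of `(a, b)` pairs with `a > b`, ties counted half).
#'
#' @param a,b Numeric samples, both non-empty.
#' @param exact_max Largest pooled n for the exact branch.
#' @return A `test_result`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 20) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  mu <- n1 * n2 / 2
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (N <= exact_max) {
    cmb <- utils::combn(N, n1)
    Us <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
  } else {
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all values tied
    } else {
      # continuity-corrected, matching the exact branch to ~2 decimals
      z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  new_test_result("Mann-Whitney U", U, min(p, 1), c(n_a = n1, n_b = n2))
}

#' Fisher's exact test on a 2x2 table (two-sided)
#'
#' Exact hypergeometric null with both margins fixed; the two-sided p-value
#' sums the probabilities of all tables no more probable than the observed
#' one (the standard convention).
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return A `test_result` (statistic = observed count in cell `[1,1]`).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins must be positive")
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  a <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  dobs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= dobs * (1 + 1e-7)])
  new_test_result("Fisher's exact", a, min(p, 1), as.vector(tab))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' One degree of freedom, no continuity correction ("standard two by two
#' table"); p from the chi-squared survival function.
#'
#' @param tab 2x2 matrix of non-negative counts; all expected counts must be
#'   positive.
#' @return A `test_result`.
#' @export
chi2_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(E <= 0)) stop("zero expected count")
  stat <- sum((tab - E)^2 / E)
  new_test_result("Pearson chi-squared (1 df)", stat,
                  stats::pchisq(stat, df = 1, lower.tail = FALSE),
                  as.vector(tab))
}

#' t-based confidence interval for a mean over preparations
#'
#' Interval on the per-preparation means (each preparation contributes one
#' value), as used for the confidence bands of the bolus state profiles.
#'
#' @param means Numeric vector of per-preparation means (length >= 2).
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(mean, lower, upper)`.
#' @export
mean_ci <- function(means, level = 0.95) {
  n <- length(means)
  if (n < 2) stop("need at least 2 preparations")
  m <- mean(means)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(means) / sqrt(n)
  c(mean = m, lower = m - half, upper = m + half)
}
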