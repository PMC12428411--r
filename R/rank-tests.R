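#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples. The statistic is the
#' conventional U for the first sample — the number of pairs with
#' `a > b` plus half the tied pairs. For small tie-free samples (both
#' n <= 8 under `mode = "auto"`) the p-value is exact, from the
#' enumeration null distribution of U over all equally likely rank
#' assignments; otherwise a normal approximation with tie-corrected
#' variance and continuity correction is used.
#'
#' @param a,b Non-empty numeric samples.
#' @param mode `"auto"` (default), `"exact"` (requires no ties) or
#'   `"normal_approx"`.
#' @return One-row tibble: `statistic` (U), `p_value`, `method`, `n_a`,
#'   `n_b`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  stop_if_not(length(a) >= 1 && length(b) >= 1 && is.numeric(a) && is.numeric(b),
              "Both samples must be non-empty numeric vectors.")
  n_a <- length(a)
  n_b <- length(b)
  r <- rank(c(a, b))
  ties <- any(duplicated(c(a, b)))
  # U for sample a: #pairs (a > b) + half ties
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2

  use_exact <- switch(mode,
    exact = {
      stop_if_not(!ties, "Exact mode requires tie-free samples.")
      TRUE
    },
    normal_approx = FALSE,
    auto = n_a <= 8 && n_b <= 8 && !ties
  )

  if (use_exact) {
    # null distribution of U is the (tie-free) Wilcoxon count distribution
    p_le <- pwilcox(u, n_a, n_b)
    p_ge <- 1 - pwilcox(u - 1, n_a, n_b)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    N <- n_a + n_b
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n_a * n_b / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      rlang::warn("All observations tied; p-value is 1.")
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
    }
    method <- "normal_approx"
  }
  tibble(statistic = u, p_value = p, method = method, n_a = n_a, n_b = n_b)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H comparing k >= 2 groups, with the
#' chi-square reference distribution on k - 1 degrees of freedom.
#'
#' @param x Numeric values.
#' @param g Grouping vector aligned with `x` (>= 2 non-empty groups
#'   after dropping missing values).
#' @return One-row tibble: `statistic` (H), `p_value`, `df`, `n_groups`,
#'   `n_total`.
#' @export
kruskal_wallis <- function(x, g) {
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]
  g <- factor(g[keep])
  g <- droplevels(g)
  k <- nlevels(g)
  N <- length(x)
  stop_if_not(k >= 2, "Need at least two non-empty groups.")
  stop_if_not(N >= 3, "Need at least three observations in total.")
  r <- rank(x)
  n_i <- tabulate(g)
  rbar <- tapply(r, g, mean)
  h_raw <- 12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)
  tie_tab <- table(x)
  correction <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (correction <= 0) {
    rlang::warn("All observations identical; H = 0, p = 1.")
    h <- 0
    p <- 1
  } else {
    h <- h_raw / correction
    p <- pchisq(h, df = k - 1, lower.tail = FALSE)
  }
  tibble(statistic = h, p_value = p, df = k - 1, n_groups = k, n_total = N)
}

#' Chi-square test of independence
#'
#' Pearson chi-square on an r x c contingency table of non-negative
#' counts, expected counts from the margins, `(r-1)(c-1)` degrees of
#' freedom. No continuity correction by default; set `correct = TRUE`
#' for the Yates-corrected 2 x 2 variant. Warns when any expected count
#' falls below 5.
#'
#' @param table Matrix of non-negative integer counts with positive row
#'   and column sums.
#' @param correct Apply the Yates continuity correction (default
#'   `FALSE`)?
#' @return One-row tibble: `statistic`, `p_value`, `df`.
#' @examples
#' chi_square_test(matrix(c(10, 0, 0, 10), 2)) # chi2 = 20, df = 1
#' @export
chi_square_test <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stop_if_not(is.numeric(table) && all(table >= 0) && nrow(table) >= 2 &&
                ncol(table) >= 2,
              "`table` must be an r x c matrix of non-negative counts.")
  rs <- rowSums(table)
  cs <- colSums(table)
  stop_if_not(all(rs > 0) && all(cs > 0),
              "Contingency table has a zero row or column margin.")
  n <- sum(table)
  expected <- outer(rs, cs) / n
  if (any(expected < 5)) {
    rlang::warn("Some expected counts are below 5; the chi-square approximation may be poor.")
  }
  dev <- abs(table - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  tibble(statistic = stat, p_value = pchisq(stat, df, lower.tail = FALSE),
         df = df)
}
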