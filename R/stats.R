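#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two samples, the test used for every
#' distributional comparison in the package. The null distribution is
#' enumerated exactly for small tie-free inputs (n1 + n2 <= 16) and
#' approximated normally with continuity correction otherwise, via
#' [stats::wilcox.test()].
#'
#' @param x,y numeric samples (both non-empty).
#' @return list with `U` (statistic for `x`), `p` (two-sided), `n1`, `n2`,
#'   and `direction` ("x", "y" or "equal": which sample has the larger
#'   median).
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n1 + n2) <= 16L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  mx <- stats::median(x); my <- stats::median(y)
  p <- wt$p.value
  if (!is.finite(p)) p <- 1   # degenerate case: zero rank variance
  list(U = unname(wt$statistic), p = min(p, 1), n1 = n1, n2 = n2,
       direction = if (mx > my) "x" else if (my > mx) "y" else "equal")
}

#' Two-sample proportion test
#'
#' Chi-squared two-sample proportion comparison with continuity
#' correction ([stats::prop.test()]).
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list with `prop1`, `prop2`, `statistic`, `p` (two-sided) and
#'   `direction`.
#' @export
proportion_test <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("both groups must be non-empty")
  pt <- suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2),
                                          correct = TRUE))
  p1 <- x1 / n1; p2 <- x2 / n2
  pv <- pt$p.value
  if (!is.finite(pv)) pv <- 1   # degenerate: both proportions 0 or 1
  list(prop1 = p1, prop2 = p2, statistic = unname(pt$statistic),
       p = pv,
       direction = if (p1 > p2) "group1" else if (p2 > p1) "group2"
                   else "equal")
}
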