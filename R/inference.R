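#' Model-II major-axis regression
#'
#' Fits the major axis of a bivariate scatter: the first principal axis of
#' the 2 x 2 covariance matrix of (x, y), appropriate when both variables
#' carry error. The slope is the ratio of the leading eigenvector's
#' components, the intercept passes the axis through the centroid, and the
#' strength and significance of the association are the squared Pearson
#' correlation and its two-sided t-test.
#'
#' @param x,y numeric vectors (n >= 3).
#' @return a [MAResult-class].
#' @examples
#' majorAxis(1:10, 2 * (1:10))  # slope 2, r^2 = 1
#' @export
majorAxis <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("major-axis regression needs at least 3 points")
  S <- stats::cov(cbind(x, y))
  if (sum(diag(S)) < 1e-24) stop("zero total variance")
  ev <- eigen(S, symmetric = TRUE)
  v <- ev$vectors[, 1]
  slope <- v[2] / v[1]
  intercept <- mean(y) - slope * mean(x)
  r <- suppressWarnings(stats::cor(x, y))
  p <- if (is.na(r) || abs(r) == 1) {
    if (is.na(r)) NA_real_ else 0
  } else suppressWarnings(stats::cor.test(x, y)$p.value)
  new("MAResult", slope = slope, intercept = intercept,
      rSquared = if (is.na(r)) NA_real_ else r^2, p = p, n = as.integer(n))
}

#' Pearson chi-squared test of independence
#'
#' @param table 2-way contingency table of non-negative counts (no
#'   continuity correction).
#' @return a [TestResult-class] with statistic "X2" and
#'   df = (r - 1)(c - 1).
#' @export
chiSquareIndependence <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal row or column")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  new("TestResult", statisticName = "X2",
      statistic = unname(ct$statistic), df = unname(ct$parameter),
      p = ct$p.value)
}

#' Fisher's exact test (2 x 2)
#'
#' Two-sided p-value by summation of hypergeometric probabilities not
#' exceeding that of the observed table; used in place of the chi-squared
#' test for small samples.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return a [TestResult-class] with statistic "Fisher-p".
#' @export
fisherExact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  p <- stats::fisher.test(table)$p.value
  new("TestResult", statisticName = "Fisher-p", statistic = p,
      df = NA_real_, p = p)
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a difference between two groups with asymmetrically
#' distributed continuous data. Reports U as the smaller of the two group
#' statistics (the common reporting convention); the p-value is exact
#' (enumeration) when `n_x * n_y <= 400` and there are no ties, otherwise
#' from the normal approximation with tie correction.
#'
#' @param x,y numeric vectors.
#' @return a [TestResult-class] with statistic "U".
#' @export
mannWhitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 1, ny >= 1)
  r <- rank(c(x, y))
  Ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  Uy <- nx * ny - Ux
  ties <- anyDuplicated(c(x, y)) > 0
  p <- suppressWarnings(stats::wilcox.test(
    x, y, exact = (nx * ny <= 400) && !ties, correct = FALSE)$p.value)
  new("TestResult", statisticName = "U", statistic = min(Ux, Uy),
      df = NA_real_, p = p)
}
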