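#' Cohen's kappa for two paired categorical ratings
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the marginal label frequencies of the two
#' raters. When both raters agree perfectly and chance agreement is 1
#' (both constant and identical), kappa is reported as 1.
#'
#' @param labels_a,labels_b Equal-length vectors (length >= 2) of
#'   categorical labels.
#' @return A single kappa value.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label sequences must have equal length")
  n <- length(labels_a)
  stopifnot(n >= 2)
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  tab <- table(a, b) / n
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (1 - p_e < .Machine$double.eps) {
    if (p_o >= 1 - .Machine$double.eps) return(1)
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Two-way random-effects single-measure absolute-agreement ICC
#'
#' ICC(A,1) in the Shrout-Fleiss/McGraw-Wong taxonomy, from the mean
#' squares of a subjects-by-raters two-way decomposition with k = 2
#' raters:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param values_a,values_b Paired continuous measurements (n >= 3).
#' @return The ICC, or `NA` when the total variance is zero.
#' @export
icc_two_way <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 3)
  n <- length(values_a)
  k <- 2
  x <- cbind(values_a, values_b)
  grand <- mean(x)
  if (sum((x - grand)^2) < .Machine$double.eps) return(NA_real_)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)          # subjects
  msc <- n * sum((col_m - grand)^2) / (k - 1)          # raters
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Two-way consistency ICC (alternative form)
#'
#' ICC(C,1): `(MSR - MSE) / (MSR + (k-1) MSE)`; insensitive to a constant
#' offset between raters.
#'
#' @inheritParams icc_two_way
#' @return The ICC, or `NA` when degenerate.
#' @export
icc_consistency <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 3)
  n <- length(values_a)
  k <- 2
  x <- cbind(values_a, values_b)
  grand <- mean(x)
  if (sum((x - grand)^2) < .Machine$double.eps) return(NA_real_)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

#' Bland-Altman agreement analysis
#'
#' Differences are `a - b`. Limits of agreement are
#' `bias +/- 1.96 * SD(a - b)`.
#'
#' @param values_a,values_b Paired measurements (n >= 2).
#' @return List: `bias`, `sd_diff`, `loa` (lower, upper), and `table`
#'   (plot-ready data frame of per-pair means and differences).
#' @export
bland_altman <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  m <- (values_a + values_b) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd_diff = s,
       loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
       table = data.frame(mean = m, difference = d))
}
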