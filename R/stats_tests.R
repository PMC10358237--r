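#' Pooled two-sample t test (positive vs negative group)
#'
#' Equal-variance two-sample t test with `df = n_pos + n_neg - 2`. The sign
#' convention follows the study tables' column order (positive, negative):
#' the reported statistic is `(mean_neg - mean_pos) / SE`, so a variable that
#' is higher in the negative group carries a positive t.
#'
#' @param x_pos,x_neg Numeric samples for the two groups, each of size >= 2.
#' @return A `group_comparison` list: `test = "pooled_t"`, `statistic`, `df`,
#'   `p_value`, and per-group `mean`/`sd`/`n`.
#' @export
pooled_t_test <- function(x_pos, x_neg) {
  x_pos <- x_pos[is.finite(x_pos)]; x_neg <- x_neg[is.finite(x_neg)]
  if (length(x_pos) < 2 || length(x_neg) < 2)
    stop("each group needs at least 2 observations")
  if (var(x_pos) == 0 && var(x_neg) == 0)
    stop("degenerate input: zero pooled variance")
  tt <- t.test(x_neg, x_pos, var.equal = TRUE)
  structure(list(
    test = "pooled_t",
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_pos = mean(x_pos), sd_pos = sd(x_pos), n_pos = length(x_pos),
    mean_neg = mean(x_neg), sd_neg = sd(x_neg), n_neg = length(x_neg)),
    class = "group_comparison")
}

#' Pooled t test from printed group summaries
#'
#' Identical formula to [pooled_t_test()] but computed from the group means,
#' SDs and sizes, so rows of published summary tables can be checked without
#' the underlying data. Sign convention as in [pooled_t_test()]:
#' `(mean_neg - mean_pos) / SE`.
#'
#' @param mean_pos,sd_pos,n_pos,mean_neg,sd_neg,n_neg Group summaries.
#' @return A `group_comparison` list, as [pooled_t_test()].
#' @export
#' @examples
#' summary_t_test(42.1, 13.2, 68, 46.2, 11.9, 102)$statistic  # ~2.106
summary_t_test <- function(mean_pos, sd_pos, n_pos, mean_neg, sd_neg, n_neg) {
  if (n_pos < 2 || n_neg < 2) stop("each group needs n >= 2")
  if (sd_pos <= 0 || sd_neg <= 0) stop("group SDs must be > 0")
  df <- n_pos + n_neg - 2
  sp2 <- ((n_pos - 1) * sd_pos^2 + (n_neg - 1) * sd_neg^2) / df
  se <- sqrt(sp2 * (1 / n_pos + 1 / n_neg))
  t_stat <- (mean_neg - mean_pos) / se
  structure(list(
    test = "pooled_t", statistic = t_stat, df = df,
    p_value = 2 * pt(-abs(t_stat), df),
    mean_pos = mean_pos, sd_pos = sd_pos, n_pos = n_pos,
    mean_neg = mean_neg, sd_neg = sd_neg, n_neg = n_neg),
    class = "group_comparison")
}

#' Pearson chi-square test on an r x 2 contingency table
#'
#' Plain Pearson statistic `sum((O - E)^2 / E)` with expected counts from the
#' row/column margins and `df = (r - 1)(c - 1)`. No continuity correction is
#' applied, including for 2 x 2 tables. Small expected counts (< 5) are
#' permitted with a warning rather than an error, matching how the reference
#' tables were analyzed.
#'
#' @param counts Nonnegative count matrix (rows = levels, columns = groups).
#' @return A `group_comparison` list: `test = "pearson_chi2"`, `statistic`,
#'   `df`, `p_value`, `observed`, `expected`.
#' @export
#' @examples
#' pearson_chi2(matrix(c(14, 54, 22, 80), 2, 2, byrow = TRUE))$statistic
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin: every row and column must have a positive total")
  res <- suppressWarnings(chisq.test(counts, correct = FALSE))
  if (any(res$expected < 5))
    warning("expected count < 5 in ", sum(res$expected < 5),
            " cell(s); Pearson statistic reported without correction")
  structure(list(
    test = "pearson_chi2",
    statistic = unname(res$statistic), df = unname(res$parameter),
    p_value = res$p.value, observed = counts, expected = res$expected),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  lab <- if (x$test == "pooled_t") "t" else "X^2"
  cat(sprintf("%s = %.3f, df = %s, p = %.4g\n", lab, x$statistic,
              format(x$df), x$p_value))
  invisible(x)
}
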