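#' Multiple linear regression with standardized coefficients
#'
#' Ordinary least squares of a numeric outcome on one or more predictors,
#' with an intercept. For each term the unstandardized coefficient B, its
#' standard error, `t = B / SE` and the two-sided p-value
#' (`df = n - p - 1`) are reported, together with the standardized
#' coefficient `beta = B * sd(x) / sd(y)` (sample SDs with n - 1), which is
#' invariant to affine rescaling of the predictor and — up to sign — to the
#' numeric coding of a binary outcome.
#'
#' @param y Numeric outcome (a binary class code is acceptable; only the
#'   standardized betas are coding-invariant).
#' @param x Data.frame or matrix of predictor columns.
#' @return A `regression_result`: data.frame with rows `(intercept)` then one
#'   per predictor, columns `term`, `B`, `SE`, `beta` (NA for the intercept),
#'   `t`, `p_value`; attributes `n`, `df`, `r_squared`.
#' @export
linear_regression_standardized <- function(y, x) {
  x <- as.data.frame(x)
  y <- as.numeric(y)
  keep <- is.finite(y) & rowSums(!is.finite(as.matrix(x))) == 0
  y <- y[keep]; x <- x[keep, , drop = FALSE]
  n <- length(y); p <- ncol(x)
  if (n <= p + 1) stop("need n > p + 1 observations")
  if (sd(y) == 0) stop("constant outcome")
  fit <- lm(y ~ ., data = cbind(data.frame(y = y), x))
  if (any(is.na(coef(fit)))) stop("rank-deficient design matrix")
  sm <- summary(fit)$coefficients
  beta <- c(NA_real_, vapply(seq_len(p), function(j)
    sm[j + 1, 1] * sd(x[[j]]) / sd(y), numeric(1)))
  out <- data.frame(term = c("(intercept)", names(x)),
                    B = sm[, 1], SE = sm[, 2], beta = beta,
                    t = sm[, 3], p_value = sm[, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, n = n, df = n - p - 1,
            r_squared = summary(fit)$r.squared,
            class = c("regression_result", "data.frame"))
}
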