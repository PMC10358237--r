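#' ROC analysis with fixed orientation and tie-corrected AUC
#'
#' Computes the area under the ROC curve as the tie-corrected rank (Mann-
#' Whitney) statistic: the fraction of (positive, negative) pairs in which
#' the positive score is higher, counting ties as half. The orientation is
#' fixed — a higher score always indicates the positive class — and an AUC
#' below 0.5 is reported as such, never flipped. The confidence interval uses
#' the Hanley-McNeil variance; the p-value tests AUC = 0.5 by a normal
#' approximation on the same variance. The operating point reported is the
#' Youden-maximizing threshold (rule "score >= threshold is called
#' positive"), and the full coordinate list over all observed thresholds is
#' always included, since published sensitivity/specificity pairs do not
#' always correspond to the Youden point.
#'
#' @param scores Numeric (or ordinal integer-coded) predictor.
#' @param labels Binary labels, 1 = positive class.
#' @param conf_level Confidence level for the Hanley-McNeil interval.
#' @return A `roc_result` list: `auc`, `ci_low`, `ci_high`, `p_value`,
#'   `threshold`, `sensitivity`, `specificity`, `n_pos`, `n_neg`, and
#'   `coordinates` (data.frame of threshold/sensitivity/specificity).
#' @export
#' @examples
#' roc_auc(c(3, 2, 4, 1, 0), c(1, 1, 1, 0, 0))$auc  # 1
roc_auc <- function(scores, labels, conf_level = 0.95) {
  keep <- is.finite(scores) & !is.na(labels)
  scores <- as.numeric(scores[keep]); labels <- as.integer(labels[keep])
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  n_pos <- as.numeric(sum(labels == 1L)); n_neg <- as.numeric(sum(labels == 0L))
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  se <- hanley_mcneil_se(auc, n_pos, n_neg)
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- if (se > 0) 2 * pnorm(-abs(auc - 0.5) / se) else as.numeric(auc == 0.5)
  coords <- roc_coordinates(scores, labels)
  youden <- coords$sensitivity + coords$specificity - 1
  best <- which.max(youden)
  structure(list(
    auc = auc,
    ci_low = max(0, auc - z * se), ci_high = min(1, auc + z * se),
    p_value = p, threshold = coords$threshold[best],
    sensitivity = coords$sensitivity[best], specificity = coords$specificity[best],
    n_pos = n_pos, n_neg = n_neg, coordinates = coords),
    class = "roc_result")
}

hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  sqrt(max(v, 0))
}

# sens/spec at every rule "score >= t" for t over the observed scores,
# plus the degenerate all-negative rule; cumulative counts keep it O(n log n)
roc_coordinates <- function(scores, labels) {
  thr <- sort(unique(scores))
  k <- length(thr)
  pos_tab <- tabulate(match(scores[labels == 1L], thr), k)
  neg_tab <- tabulate(match(scores[labels == 0L], thr), k)
  sens <- rev(cumsum(rev(pos_tab))) / sum(pos_tab)
  spec <- c(0, cumsum(neg_tab)[-k]) / sum(neg_tab)
  data.frame(threshold = c(thr, Inf), sensitivity = c(sens, 0),
             specificity = c(spec, 1))
}

#' Closed-form binormal AUC
#'
#' The ROC area when both class score distributions are normal:
#' `pnorm((mean_pos - mean_neg) / sqrt(sd_pos^2 + sd_neg^2))`, under the same
#' fixed orientation as [roc_auc()] (higher score indicates the positive
#' class). Connects published group summaries to published AUCs.
#'
#' @param mean_pos,sd_pos Mean and SD of the positive-class scores.
#' @param mean_neg,sd_neg Mean and SD of the negative-class scores.
#' @return The AUC (scalar in `[0, 1]`).
#' @export
#' @examples
#' binormal_auc(-0.50, 0.13, -0.55, 0.12)  # ~0.611
binormal_auc <- function(mean_pos, sd_pos, mean_neg, sd_neg) {
  if (sd_pos <= 0 || sd_neg <= 0) stop("SDs must be > 0")
  pnorm((mean_pos - mean_neg) / sqrt(sd_pos^2 + sd_neg^2))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (%.0f%% CI %.3f-%.3f), p = %.4g; Youden point: thr %.4g, sens %.1f%%, spec %.1f%%\n",
              x$auc, 95, x$ci_low, x$ci_high, x$p_value, x$threshold,
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}
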