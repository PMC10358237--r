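# Independent brute-force oracles and small shared fixtures.

# literal Higuchi curve-length construction, kept loop-by-loop
higuchi_brute <- function(x, k_max = 8L) {
  n <- length(x)
  L <- numeric(k_max)
  for (k in seq_len(k_max)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      nseg <- floor((n - m) / k)
      s <- 0
      for (i in seq_len(nseg)) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      Lm[m] <- (s * (n - 1) / (nseg * k)) / k
    }
    L[k] <- mean(Lm)
  }
  -unname(coef(lm(y ~ k, data = data.frame(y = log(L), k = log(seq_len(k_max)))))[2])
}

# Pearson statistic straight from its definition
chi2_brute <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# AUC by full pairwise enumeration with half-credit ties
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# small, fast acquisition geometry used throughout the unit tests
small_acq <- function(lines = 64L, samples = 1024L, frames = 4L)
  acquisition_config(lines_per_frame = lines, samples_per_line = samples,
                     n_frames = frames)

small_roi <- function() roi_spec(10, 50, 300, 812)

small_phantom <- function(..., roi = small_roi())
  phantom_config(nodule_region = roi, ...)

frame_values <- function(frame) unclass(frame)[, , drop = FALSE]
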