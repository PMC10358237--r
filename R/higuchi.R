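#' Higuchi fractal dimension of a series
#'
#' The curve-length roughness estimator of a 1-D series: for each lag
#' k = 1..k_max and offset m = 1..k, the decimated curve length is
#' \deqn{L_m(k) = \frac{1}{k}\left[\sum_{i=1}^{\lfloor (n-m)/k \rfloor}
#'   |x(m+ik) - x(m+(i-1)k)|\right] \frac{n-1}{\lfloor (n-m)/k \rfloor\, k},}
#' L(k) is the mean of L_m(k) over offsets, and the fractal dimension is the
#' negated slope of the OLS fit of ln L(k) against ln k. Smooth curves give
#' values near 1; white noise approaches 2. The estimator is invariant to
#' affine rescaling of the series.
#'
#' @param x Numeric series, length at least `10 * k_max`.
#' @param k_max Largest decimation lag (default 8, a common choice for RF
#'   segments of a few hundred to a few thousand samples).
#' @return The estimated fractal dimension (scalar).
#' @export
#' @examples
#' higuchi_fd(seq_len(1000))        # ~1 for a straight line
higuchi_fd <- function(x, k_max = 8L) {
  x <- as.numeric(x)
  n <- length(x)
  k_max <- as.integer(k_max)
  if (k_max < 2L) stop("k_max must be >= 2")
  if (n < 10L * k_max)
    stop(sprintf("series too short: need length >= %d for k_max = %d", 10L * k_max, k_max))
  if (all(x == x[1])) stop("degenerate input: constant series has no curve length")
  lk <- vapply(seq_len(k_max), function(k) {
    lm_k <- vapply(seq_len(k), function(m) {
      idx <- seq.int(m, n, by = k)
      nseg <- length(idx) - 1L
      sum(abs(diff(x[idx]))) * (n - 1) / (nseg * k) / k
    }, numeric(1))
    mean(lm_k)
  }, numeric(1))
  fit <- lm(ll ~ lk, data = data.frame(ll = log(lk), lk = log(seq_len(k_max))))
  -unname(coef(fit)[2])
}

#' ROI-averaged Higuchi fractal dimension
#'
#' Applies [higuchi_fd()] to every scan line's raw RF segment inside the ROI
#' and averages the per-line estimates. The estimator runs on the raw RF
#' series, not on the spectrum.
#'
#' @param frame An `rf_frame` matrix.
#' @param roi An [roi_spec()] inside the frame.
#' @param k_max Largest decimation lag, passed to [higuchi_fd()].
#' @return Mean per-line fractal dimension (scalar).
#' @export
roi_higuchi <- function(frame, roi, k_max = 8L) {
  validate_roi(roi, nrow(frame), ncol(frame))
  cols <- (roi$sample_start + 1L):roi$sample_stop
  fds <- vapply((roi$line_start + 1L):roi$line_stop, function(i)
    higuchi_fd(frame[i, cols], k_max), numeric(1))
  mean(fds)
}
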