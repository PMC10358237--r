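#' Mean power spectrum of an ROI
#'
#' For every scan line crossing the ROI, the ROI-depth segment is windowed,
#' zero-padded to `n_fft` points and Fourier transformed; the magnitudes
#' `|X[k]|`, k = 1..N/2, are then averaged elementwise across lines. This is
#' the standard per-line quantitative-ultrasound spectrum estimate: one FFT
#' per A-line segment, no overlap. The zero-frequency bin is excluded; the
#' frequency axis is the normalized f_k = k/N in cycles/sample over (0, 0.5].
#'
#' @param frame An `rf_frame` matrix (`[lines x samples]`) or plain matrix.
#' @param roi An [roi_spec()] inside the frame.
#' @param n_fft FFT length N; defaults to the next power of two at or above
#'   the ROI depth extent. Must be at least the segment length.
#' @param window `"hann"` (default, leakage control) or `"rectangular"`.
#' @param power If `TRUE` average `|X[k]|^2` instead of `|X[k]|`. The default
#'   averages magnitudes, the convention under which the published mid-band
#'   and sub-band values are mutually consistent.
#' @return Numeric vector of length `n_fft / 2` with attributes `n_fft` and
#'   `freq` (the normalized frequency axis).
#' @export
roi_power_spectrum <- function(frame, roi, n_fft = NULL,
                               window = c("hann", "rectangular"),
                               power = FALSE) {
  window <- match.arg(window)
  validate_roi(roi, nrow(frame), ncol(frame))
  seg_len <- roi$sample_stop - roi$sample_start
  if (is.null(n_fft)) n_fft <- 2^ceiling(log2(seg_len))
  n_fft <- as.integer(n_fft)
  if (n_fft < seg_len) stop("n_fft must be >= the ROI sample extent")
  w <- if (window == "hann") as.numeric(signal::hanning(seg_len)) else rep(1, seg_len)
  lines <- (roi$line_start + 1L):roi$line_stop
  cols <- (roi$sample_start + 1L):roi$sample_stop
  half <- n_fft %/% 2L
  acc <- numeric(half)
  pad <- numeric(n_fft - seg_len)
  for (i in lines) {
    x <- c(as.numeric(frame[i, cols]) * w, pad)
    mag <- Mod(fft(x))[2:(half + 1L)]  # k = 1..N/2, DC excluded
    acc <- acc + if (power) mag^2 else mag
  }
  spec <- acc / length(lines)
  attr(spec, "n_fft") <- n_fft
  attr(spec, "freq") <- seq_len(half) / n_fft
  spec
}

#' Normalize a mean power spectrum to unit maximum
#'
#' Divides elementwise by the spectral maximum so the largest component is
#' exactly 1 and all components lie in `[0, 1]`; the shape is unchanged.
#'
#' @param raw Nonnegative numeric vector (a mean power spectrum), as from
#'   [roi_power_spectrum()].
#' @return A `normalized_spectrum`: numeric vector with max exactly 1,
#'   carrying `n_fft` and `freq` attributes when present on the input.
#' @export
#' @examples
#' normalize_spectrum(c(1, 2, 4, 2))  # 0.25 0.50 1.00 0.50
normalize_spectrum <- function(raw) {
  m <- max(raw)
  if (!is.finite(m) || m <= 0)
    stop("degenerate ROI: spectrum has no positive component to normalize by")
  out <- raw / m
  attributes(out) <- attributes(raw)
  class(out) <- "normalized_spectrum"
  out
}

# normalized frequency axis of a spectrum vector (fall back to k/N by length)
spectrum_freq <- function(spec) {
  f <- attr(spec, "freq")
  if (is.null(f)) f <- seq_along(spec) / (2 * length(spec))
  f
}

#' Straight-line fit to a normalized spectrum
#'
#' Ordinary least squares of the normalized spectral values against normalized
#' frequency f_k = k/N over the bins inside `band`. Three coefficients are
#' reported: `slope` (per cycle/sample), `intercept` (fitted value at f = 0),
#' and `mid_band` (fitted value at the band midpoint, so with the default
#' full-axis band `mid_band = intercept + 0.25 * slope`).
#'
#' @param spec A `normalized_spectrum` (any numeric vector with a `freq`
#'   attribute, or of length N/2, is accepted).
#' @param band Numeric `c(f_lo, f_hi)` within (0, 0.5]; default the full axis.
#' @return Named list `slope`, `intercept`, `mid_band`, plus `band` and the
#'   number of bins used (`n_bins`).
#' @export
fit_spectral_line <- function(spec, band = c(0, 0.5)) {
  f <- spectrum_freq(spec)
  if (length(band) != 2 || band[1] < 0 || band[2] > 0.5 || band[1] >= band[2])
    stop("band must be c(f_lo, f_hi) within (0, 0.5]")
  keep <- f > band[1] & f <= band[2]
  if (sum(keep) < 3) stop("fewer than 3 spectral bins in the fit band")
  fit <- lm(y ~ f, data = data.frame(y = as.numeric(spec)[keep], f = f[keep]))
  b <- coef(fit)
  mid <- (band[1] + band[2]) / 2
  list(slope = unname(b[2]), intercept = unname(b[1]),
       mid_band = unname(b[1] + b[2] * mid), band = band,
       n_bins = sum(keep))
}

#' Sub-band mean powers S1-S4
#'
#' Means of the normalized spectrum over the four equal quarters of the
#' positive-frequency axis k = 1..N/2: S1 over k = 1..N/8 (low band), S2 over
#' N/8+1..N/4, S3 over N/4+1..3N/8, and S4 over 3N/8+1..N/2 (high band).
#' Means, not raw sums, so each lies in `[0, 1]` for a normalized spectrum.
#'
#' @param spec A normalized spectrum of length N/2 with N divisible by 8.
#' @return Named numeric vector `c(s1, s2, s3, s4)`.
#' @export
#' @examples
#' band_means(normalize_spectrum(c(8, 7, 6, 5, 4, 3, 2, 1)))
band_means <- function(spec) {
  half <- length(spec)
  if (half %% 4L != 0L)
    stop("spectrum length N/2 must be divisible by 4 (pad the FFT to N divisible by 8)")
  q <- half %/% 4L
  idx <- split(seq_len(half), rep(1:4, each = q))
  out <- vapply(idx, function(i) mean(as.numeric(spec)[i]), numeric(1))
  names(out) <- c("s1", "s2", "s3", "s4")
  out
}
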