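test_that("ROI spectrum behaves as a per-line FFT magnitude average", {
  # all-zero frame -> all-zero spectrum
  zero <- matrix(0, 8, 128)
  expect_true(all(roi_power_spectrum(zero, roi_spec(0, 8, 0, 128)) == 0))

  # pure cosine at f = 0.25 cycles/sample, rectangular window, matched N
  n <- 256
  frame <- matrix(cos(2 * pi * 0.25 * (0:(n - 1))), nrow = 1)
  spec <- roi_power_spectrum(frame, roi_spec(0, 1, 0, n), n_fft = n,
                             window = "rectangular")
  expect_equal(which.max(spec), n / 4)

  # averaging two lines equals the mean of their individual spectra
  set.seed(31)
  two <- matrix(rnorm(2 * 128), nrow = 2)
  roi2 <- roi_spec(0, 2, 0, 128)
  s_both <- roi_power_spectrum(two, roi2)
  s_each <- (roi_power_spectrum(two[1, , drop = FALSE], roi_spec(0, 1, 0, 128)) +
             roi_power_spectrum(two[2, , drop = FALSE], roi_spec(0, 1, 0, 128))) / 2
  expect_equal(as.numeric(s_both), as.numeric(s_each), tolerance = 1e-12)
})

test_that("normalization divides by the maximum and is idempotent", {
  expect_equal(as.numeric(normalize_spectrum(c(1, 2, 4, 2))),
               c(0.25, 0.5, 1.0, 0.5))
  once <- normalize_spectrum(c(0.3, 0.9, 0.1))
  expect_equal(as.numeric(normalize_spectrum(once)), as.numeric(once))
  set.seed(4)
  for (i in 1:10) {
    out <- normalize_spectrum(runif(64, 0.01, 5))
    expect_identical(max(out), 1)
    expect_true(all(out >= 0 & out <= 1))
  }
  expect_error(normalize_spectrum(numeric(16)), "degenerate")
})

test_that("spectral line fit recovers noiseless linear spectra exactly", {
  n <- 256
  f <- seq_len(n / 2) / n
  spec <- structure(0.8 - 0.6 * f, freq = f)
  fit <- fit_spectral_line(spec)
  expect_equal(fit$slope, -0.6, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.8, tolerance = 1e-9)
  expect_equal(fit$mid_band, 0.65, tolerance = 1e-9)

  flat <- structure(rep(1, n / 2), freq = f)
  fit_flat <- fit_spectral_line(flat)
  expect_equal(fit_flat$slope, 0, tolerance = 1e-12)
  expect_equal(fit_flat$intercept, 1, tolerance = 1e-12)
  expect_equal(fit_flat$mid_band, 1, tolerance = 1e-12)

  # mid-band is always the fitted value at the band midpoint
  set.seed(9)
  noisy <- structure(runif(n / 2), freq = f)
  fit_n <- fit_spectral_line(noisy, band = c(0.1, 0.4))
  expect_equal(fit_n$mid_band, fit_n$intercept + fit_n$slope * 0.25,
               tolerance = 1e-12)
  expect_error(fit_spectral_line(spec, band = c(0.2, 0.21)), "fewer than 3")
})

test_that("published slope/intercept/mid-band triplets are consistent at f = 0.25", {
  refs <- clnm_reference_summaries()
  pick <- function(nm, col) refs[refs$name == nm, col]
  for (sec in c("trans", "long")) for (grp in c("pos", "neg")) {
    ic <- pick(paste0(sec, "_intercept"), paste0("mean_", grp))
    sl <- pick(paste0(sec, "_slope"), paste0("mean_", grp))
    mb <- pick(paste0(sec, "_mid_band"), paste0("mean_", grp))
    expect_lte(abs(ic + 0.25 * sl - mb), 0.02)
  }
})

test_that("sub-band means cover the axis in quarters and stay in [0, 1]", {
  expect_equal(unname(band_means(rep(1, 64))), c(1, 1, 1, 1))
  ind <- c(rep(1, 8), rep(0, 24))  # N = 64: energy only in the low band
  expect_equal(unname(band_means(ind)), c(1, 0, 0, 0))
  # N = 16 worked example
  s <- band_means(c(8, 7, 6, 5, 4, 3, 2, 1) / 8)
  expect_equal(unname(s), c(0.9375, 0.6875, 0.4375, 0.1875))
  expect_error(band_means(rep(1, 10)), "divisible")
  set.seed(12)
  for (i in 1:10) {
    s <- band_means(normalize_spectrum(runif(32, 0.01, 2)))
    expect_true(all(s >= 0 & s <= 1))
  }
})
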