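test_that("empty phantom yields an all-zero frame", {
  fr <- simulate_rf_frame(phantom_config(scatterer_density = 0, noise_sd = 0),
                          small_acq(), seed = 1)
  expect_true(all(frame_values(fr) == 0))
})

test_that("frames are deterministic in the seed", {
  ph <- small_phantom(noise_sd = 0.05)
  acq <- small_acq()
  expect_identical(frame_values(simulate_rf_frame(ph, acq, 42)),
                   frame_values(simulate_rf_frame(ph, acq, 42)))
  expect_false(identical(frame_values(simulate_rf_frame(ph, acq, 42)),
                         frame_values(simulate_rf_frame(ph, acq, 43))))
})

test_that("simulated backscatter is centered in the receive passband", {
  acq <- small_acq()
  fr <- simulate_rf_frame(small_phantom(noise_sd = 0), acq, seed = 5)
  roi <- small_roi()
  spec <- roi_power_spectrum(fr, roi)
  peak_hz <- attr(spec, "freq")[which.max(spec)] * acq$sampling_rate_hz
  expect_lt(abs(peak_hz - acq$rx_center_frequency_hz), 1.5e6)
})

test_that("a nodule region outside the frame grid is rejected", {
  bad <- roi_spec(0, 400, 0, 512)  # 400 lines > 64-line frame
  expect_error(
    simulate_rf_frame(phantom_config(nodule_region = bad), small_acq(), 1),
    "exceeds frame extent")
})

test_that("a case has two sections with the configured frame geometry", {
  acq <- acquisition_config(samples_per_line = 256L)  # 312 lines, 20 frames
  case <- simulate_case(small_phantom(roi = roi_spec(50, 250, 16, 200)), acq, 9)
  expect_named(case$sections, c("transverse", "longitudinal"))
  expect_length(case$sections$transverse, 20L)
  expect_equal(nrow(case$sections$transverse[[1]]), 312L)
  case2 <- simulate_case(small_phantom(roi = roi_spec(50, 250, 16, 200)), acq, 9)
  expect_identical(case$sections, case2$sections)
})

test_that("sections are independent; frames within a section differ only by noise", {
  ph <- small_phantom(noise_sd = 0.05)
  case <- simulate_case(ph, small_acq(frames = 3L), 21)
  tr <- case$sections$transverse
  lo <- case$sections$longitudinal
  expect_false(any(frame_values(tr[[1]]) == frame_values(lo[[1]])))
  expect_false(identical(frame_values(tr[[1]]), frame_values(tr[[2]])))
  # noiseless case: frames within a section are the shared scatterer field
  quiet <- simulate_case(small_phantom(noise_sd = 0), small_acq(frames = 3L), 21)
  expect_identical(frame_values(quiet$sections$transverse[[1]]),
                   frame_values(quiet$sections$transverse[[3]]))
})

test_that("scatterer density separates fitted slopes with a consistent sign", {
  acq <- small_acq()
  roi <- small_roi()
  diffs <- vapply(1:20, function(s) {
    lo <- small_phantom(scatterer_density = 0.01, noise_sd = 0.05)
    hi <- small_phantom(scatterer_density = 0.16, noise_sd = 0.05)
    extract_roi_features(simulate_rf_frame(lo, acq, s), roi)[["slope"]] -
      extract_roi_features(simulate_rf_frame(hi, acq, s), roi)[["slope"]]
  }, numeric(1))
  expect_true(all(diffs > 0))  # sparse field -> lower SNR -> shallower slope
})
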