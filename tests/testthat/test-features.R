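make_quiet_case <- function(seed = 7, frames = 4L) {
  simulate_case(small_phantom(noise_sd = 0), small_acq(frames = frames), seed)
}

test_that("identical readers and identical frames reduce to a single-ROI result", {
  case <- make_quiet_case()
  roi <- small_roi()
  single <- extract_roi_features(case$sections$transverse[[2]], roi)
  # noiseless case: all frames equal, both readers share the ROI
  feats <- extract_case_features(case, typical_frame = 3)
  expect_equal(unlist(feats[feats$section == "transverse", -1]), single,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("reader averaging is the parameterwise mean of the two readers", {
  case <- make_quiet_case(seed = 19)
  roi_a <- roi_spec(10, 40, 300, 812)
  roi_b <- roi_spec(20, 55, 280, 792)
  fr <- case$sections$longitudinal[[2]]
  a <- extract_roi_features(fr, roi_a)
  b <- extract_roi_features(fr, roi_b)
  feats <- extract_case_features(
    case, rois = list(transverse = roi_a,
                      longitudinal = list(roi_a, roi_b)),
    typical_frame = 2)
  expect_equal(unlist(feats[feats$section == "longitudinal", -1]), (a + b) / 2,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("frame averaging spans the typical frame and its neighbours", {
  case <- simulate_case(small_phantom(noise_sd = 0.05), small_acq(frames = 5L), 23)
  roi <- small_roi()
  per_frame <- vapply(2:4, function(f)
    extract_roi_features(case$sections$transverse[[f]], roi), numeric(8))
  feats <- extract_case_features(case, typical_frame = 3)
  expect_equal(unlist(feats[feats$section == "transverse", -1]),
               rowMeans(per_frame), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("boundary typical frames and missing ROIs are rejected", {
  case <- make_quiet_case()
  expect_error(extract_case_features(case, typical_frame = 1), "interior")
  expect_error(extract_case_features(case, typical_frame = 4), "interior")
  expect_error(extract_case_features(case, rois = list(transverse = small_roi()),
                                     typical_frame = 2), "missing reader ROI")
})

test_that("all eight features are invariant to overall amplitude scaling", {
  fr <- simulate_rf_frame(small_phantom(noise_sd = 0.02), small_acq(), 31)
  roi <- small_roi()
  f1 <- extract_roi_features(fr, roi)
  f2 <- extract_roi_features(fr * 250, roi)
  expect_equal(f1, f2, tolerance = 1e-9)
})
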