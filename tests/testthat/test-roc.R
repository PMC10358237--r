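test_that("AUC equals brute-force pair enumeration, ties included", {
  set.seed(55)
  for (i in 1:15) {
    n1 <- sample(5:40, 1); n0 <- sample(5:40, 1)
    labels <- rep(c(1L, 0L), c(n1, n0))
    scores <- sample(0:6, n1 + n0, replace = TRUE)  # heavy ties
    expect_equal(roc_auc(scores, labels)$auc, auc_brute(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("orientation is fixed: separation, complement, no flipping", {
  labels <- c(1, 1, 1, 0, 0)
  expect_equal(roc_auc(c(5, 6, 7, 1, 2), labels)$auc, 1)
  a <- roc_auc(c(1, 3, 2, 4, 5), labels)$auc
  b <- roc_auc(c(1, 3, 2, 4, 5), 1 - labels)$auc
  expect_equal(a + b, 1)
  expect_lt(a, 0.5)  # reported untouched, not flipped to 1 - a
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("ordinal echogenic-foci AUC matches the published pair statistic", {
  foci <- expand_counts(clnm_reference_counts()$echogenic_foci_code)
  res <- roc_auc(foci$code, foci$label)
  expect_equal(res$auc, (3451 + 0.5 * 3050) / 7992, tolerance = 1e-12)
  expect_equal(round(res$auc, 2), 0.62)
  expect_equal(res$auc, auc_brute(foci$code, foci$label), tolerance = 1e-12)
  expect_true(res$ci_low <= res$auc && res$auc <= res$ci_high)
  expect_lt(res$p_value, 0.05)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  set.seed(91)
  scores <- c(rnorm(60, 1), rnorm(80))
  labels <- rep(c(1L, 0L), c(60, 80))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, direction = "<",
                                        quiet = TRUE)))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-10)
})

test_that("Youden operating point and coordinates are coherent", {
  scores <- c(3, 2, 4, 1, 0, 2, 1, 5)
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0)
  res <- roc_auc(scores, labels)
  co <- res$coordinates
  youden <- co$sensitivity + co$specificity - 1
  expect_equal(res$sensitivity + res$specificity - 1, max(youden))
  expect_true(all(co$sensitivity >= 0 & co$sensitivity <= 1))
  expect_true(all(diff(co$sensitivity) <= 0))  # sens falls as threshold rises
  expect_true(all(diff(co$specificity) >= 0))
})

test_that("binormal closed form matches its identities and the empirical AUC", {
  expect_equal(binormal_auc(0, 1, 0, 1), 0.5)
  expect_equal(binormal_auc(-0.50, 0.13, -0.55, 0.12), 0.611, tolerance = 1e-3)
  a <- binormal_auc(1, 0.5, 0, 1.5)
  expect_equal(binormal_auc(0, 1.5, 1, 0.5), 1 - a)
  set.seed(17)
  scores <- c(rnorm(1e5, -0.50, 0.13), rnorm(1e5, -0.55, 0.12))
  labels <- rep(c(1L, 0L), each = 1e5)
  expect_equal(roc_auc(scores, labels)$auc,
               binormal_auc(-0.50, 0.13, -0.55, 0.12), tolerance = 0.005 / 0.61)
  expect_error(binormal_auc(0, 0, 1, 1), "SDs")
})
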