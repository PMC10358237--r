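test_that("parameter validation enforces the cohort contract", {
  expect_error(cohort_params(-1, 10), "nonnegative")
  expect_error(cohort_params(
    10, 10, categorical = list(list(name = "x", levels = c("a", "b"),
                                    counts_pos = c(5, 4), counts_neg = c(5, 5)))),
    "sum to n_pos")
  bad_cont <- data.frame(name = "v", mean_pos = 0, sd_pos = 0,
                         mean_neg = 0, sd_neg = 1)
  expect_error(cohort_params(5, 5, continuous = bad_cont), "SDs must be > 0")
})

test_that("simulation is deterministic in the seed and labels match group sizes", {
  params <- reference_cohort_params()
  a <- simulate_cohort(params, seed = 5)
  b <- simulate_cohort(params, seed = 5)
  expect_identical(a, b)
  expect_equal(sum(a$clnm == 1), 74)
  expect_equal(sum(a$clnm == 0), 108)
  expect_false(identical(a$long_slope, simulate_cohort(params, seed = 6)$long_slope))
})

test_that("an empty positive group yields an all-negative cohort", {
  params <- reference_cohort_params(n_pos = 0L, n_neg = 30L)
  cohort <- simulate_cohort(params, seed = 2)
  expect_equal(nrow(cohort), 30)
  expect_true(all(cohort$clnm == 0))
})

test_that("large-sample draws converge to the specified group parameters", {
  params <- reference_cohort_params(n_pos = 100000L, n_neg = 1000L)
  cohort <- simulate_cohort(params, seed = 11)
  pos <- cohort[cohort$clnm == 1, ]
  # longitudinal slope mean -0.50 within +/-0.01 at 1e5 pooled draws
  expect_equal(mean(pos$long_slope), -0.50, tolerance = 0.01 / 0.50)
  expect_lt(abs(mean(pos$long_slope) + 0.50), 0.01)
  # punctate echogenic-foci fraction converges to 43/74
  expect_lt(abs(mean(pos$echogenic_foci_code == 3) - 43 / 74), 0.01)
})

test_that("caliper columns are internally consistent with the drawn diameter", {
  cohort <- simulate_cohort(reference_cohort_params(), seed = 8)
  expect_equal(cohort$volume_mm3,
               nodule_volume(cohort$length_mm, cohort$height_mm, cohort$width_mm))
  expect_equal(cohort$max_diameter_mm,
               max_diameter(cohort$length_mm, cohort$height_mm, cohort$width_mm))
  expect_true(all(cohort$length_mm > 0 & cohort$width_mm > 0))
})

test_that("simulated effects reach significance at the published power level", {
  # longitudinal intercept (0.63+/-0.04 vs 0.65+/-0.05, n = 74/108): effect
  # size ~0.43 implies ~0.8 power, so well above a 0.60 floor over 200 runs
  params <- reference_cohort_params()
  hits <- vapply(1:200, function(s) {
    cohort <- simulate_cohort(params, seed = s)
    pooled_t_test(cohort$long_intercept[cohort$clnm == 1],
                  cohort$long_intercept[cohort$clnm == 0])$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.60)
})
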