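test_that("a null single-variable cohort leaves stages 2 and 3 empty", {
  set.seed(71)
  cohort <- data.frame(clnm = rep(c(1, 0), each = 40), x = rnorm(80))
  rep0 <- run_association_cascade(cohort, continuous = "x",
                                  categorical = character())
  expect_equal(nrow(rep0$univariate), 1)
  expect_gt(rep0$univariate$p_value, 0.05)
  expect_equal(nrow(rep0$roc), 0)
  expect_null(rep0$regression)
})

test_that("the cascade is a pure function of the cohort table", {
  cohort <- simulate_cohort(reference_cohort_params(), seed = 3)
  set.seed(1); a <- run_association_cascade(cohort)
  set.seed(999); b <- run_association_cascade(cohort)
  expect_identical(a$univariate, b$univariate)
  expect_identical(a$roc, b$roc)
  expect_identical(a$stage3_vars, b$stage3_vars)
})

test_that("stage gates apply p < alpha then AUC > gate on fixed orientation", {
  set.seed(72)
  n <- 120
  cohort <- data.frame(clnm = rep(c(1L, 0L), each = n / 2))
  cohort$up <- rnorm(n, ifelse(cohort$clnm == 1, 1.5, 0))    # strong, AUC > 0.5
  cohort$down <- rnorm(n, ifelse(cohort$clnm == 1, 0, 1.5))  # strong, AUC < 0.5
  cohort$null <- rnorm(n)
  res <- run_association_cascade(cohort, continuous = c("up", "down", "null"),
                                 categorical = character())
  expect_setequal(res$stage2_vars, c("up", "down"))
  expect_equal(res$stage3_vars, "up")  # AUC < 0.5 never flipped into stage 3
  expect_equal(res$regression$term, c("(intercept)", "up"))
})

test_that("standardized betas are invariant to the outcome coding", {
  cohort <- simulate_cohort(reference_cohort_params(), seed = 12)
  a <- run_association_cascade(cohort, outcome_codes = c(1, 2))
  b <- run_association_cascade(cohort, outcome_codes = c(0, 1))
  if (!is.null(a$regression)) {
    expect_equal(a$regression$beta, b$regression$beta, tolerance = 1e-10)
    expect_equal(a$regression$t[-1], b$regression$t[-1], tolerance = 1e-10)
  }
})

test_that("variables with true AUC > 0.5 dominate stage 3 across seeded runs", {
  params <- reference_cohort_params()
  runs <- lapply(1:100, function(s)
    run_association_cascade(simulate_cohort(params, seed = 1000 + s))$stage3_vars)
  hit <- function(v) mean(vapply(runs, function(r) v %in% r, logical(1)))
  # floors from a priori power at the published effect sizes
  expect_gte(hit("max_diameter_mm"), 0.90)      # |t| = 4.36 -> power ~0.99
  expect_gte(hit("echogenic_foci_code"), 0.50)  # chi2 = 11.8 (df 3)
  expect_gte(hit("long_slope"), 0.40)           # |t| = 2.30 -> power ~0.63
  # variables whose published AUC is below 0.5 cannot pass the AUC gate
  for (v in c("age_years", "long_intercept", "long_higuchi", "trans_s1"))
    expect_lte(hit(v), 0.02)
})
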