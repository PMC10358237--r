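#' Published study summaries for the PTC/CLNM reference cohort
#'
#' Group-level summary statistics of the clinical papillary-thyroid-carcinoma
#' cohort the simulator emulates: 74 CLNM-positive and 108 CLNM-negative
#' nodules (182 nodules from 170 patients). `clnm_reference_summaries()`
#' returns the continuous per-group means and SDs (age, tumor maximum
#' diameter, and the sixteen RF spectral parameters in both sections);
#' `clnm_reference_counts()` returns the per-group level counts of the
#' categorical sonographic variables. Patient-level variables (sex and the
#' 55-year age split) are tabulated over the 68/102 patient groups; all other
#' tables are nodule-level over 74/108.
#'
#' The diameter group means are not printed in the source tables; they are
#' derived here from the published overall summary (9.69 +/- 7.50 mm) and the
#' published pooled-t statistic (|t| = 4.361), giving 12.62 mm vs 7.69 mm at a
#' common 7.50 mm SD — values that also reproduce the published diameter AUC
#' of 0.68 under a binormal model.
#'
#' @return `clnm_reference_summaries()`: data.frame with columns `name`,
#'   `mean_pos`, `sd_pos`, `mean_neg`, `sd_neg`, `n_pos`, `n_neg`.
#'   `clnm_reference_counts()`: named list of categorical specs (`name`,
#'   `levels`, `counts_pos`, `counts_neg`).
#' @export
clnm_reference_summaries <- function() {
  tab <- rbind(
    c("age_years",        42.10, 13.20, 46.20, 11.90),
    c("max_diameter_mm",  12.62,  7.50,  7.69,  7.50),
    c("trans_higuchi",     2.61,  0.13,  2.63,  0.12),
    c("trans_slope",      -0.52,  0.13, -0.55,  0.12),
    c("trans_intercept",   0.64,  0.04,  0.65,  0.05),
    c("trans_mid_band",    0.50,  0.05,  0.52,  0.07),
    c("trans_s1",          0.10,  0.04,  0.12,  0.04),
    c("trans_s2",          0.18,  0.05,  0.17,  0.05),
    c("trans_s3",          0.07,  0.03,  0.07,  0.03),
    c("trans_s4",          0.02,  0.01,  0.03,  0.02),
    c("long_higuchi",      2.58,  0.13,  2.63,  0.11),
    c("long_slope",       -0.50,  0.13, -0.55,  0.12),
    c("long_intercept",    0.63,  0.04,  0.65,  0.05),
    c("long_mid_band",     0.49,  0.05,  0.51,  0.07),
    c("long_s1",           0.10,  0.04,  0.11,  0.04),
    c("long_s2",           0.18,  0.05,  0.17,  0.05),
    c("long_s3",           0.07,  0.03,  0.07,  0.03),
    c("long_s4",           0.02,  0.01,  0.03,  0.01))
  out <- data.frame(name = tab[, 1],
                    mean_pos = as.numeric(tab[, 2]), sd_pos = as.numeric(tab[, 3]),
                    mean_neg = as.numeric(tab[, 4]), sd_neg = as.numeric(tab[, 5]),
                    stringsAsFactors = FALSE)
  # age and the patient-level tables use the 68/102 patient split
  out$n_pos <- ifelse(out$name == "age_years", 68L, 74L)
  out$n_neg <- ifelse(out$name == "age_years", 102L, 108L)
  out
}

#' @rdname clnm_reference_summaries
#' @export
clnm_reference_counts <- function() {
  list(
    sex = list(
      name = "sex", levels = c("male", "female"),
      counts_pos = c(14, 54), counts_neg = c(22, 80)),
    age_ge55 = list(
      name = "age_ge55", levels = c("ge55", "lt55"),
      counts_pos = c(12, 56), counts_neg = c(26, 76)),
    location_code = list(
      name = "location_code",
      levels = c("left_upper", "left_middle", "left_lower", "right_upper",
                 "right_middle", "right_lower", "isthmus"),
      counts_pos = c(6, 19, 8, 9, 16, 12, 4),
      counts_neg = c(6, 34, 10, 9, 35, 11, 3)),
    echogenicity_code = list(
      name = "echogenicity_code", levels = c("hypoechoic", "very_hypoechoic"),
      counts_pos = c(74, 0), counts_neg = c(106, 2)),
    ar_ge1 = list(
      name = "ar_ge1", levels = c("lt1", "ge1"),
      counts_pos = c(28, 46), counts_neg = c(33, 75)),
    margin_code = list(
      name = "margin_code",
      levels = c("smooth_or_ill_defined", "lobulated_or_irregular"),
      counts_pos = c(43, 31), counts_neg = c(71, 37)),
    echogenic_foci_code = list(
      name = "echogenic_foci_code",
      levels = c("none_or_comet_tail", "macrocalcification", "peripheral",
                 "punctate"),
      counts_pos = c(21, 10, 0, 43), counts_neg = c(57, 9, 1, 41)),
    flow_grade = list(
      name = "flow_grade", levels = c("0", "1", "2", "3", "4"),
      counts_pos = c(36, 22, 11, 4, 1), counts_neg = c(65, 32, 8, 2, 1)),
    elasticity_score = list(
      name = "elasticity_score", levels = c("2", "3", "4", "5"),
      counts_pos = c(0, 35, 37, 2), counts_neg = c(1, 56, 49, 2)))
}

#' Default cohort parameters emulating the reference study
#'
#' Assembles a [cohort_params()] object at the published study conditions:
#' 74 CLNM-positive and 108 CLNM-negative nodules, continuous variables at
#' the published group means/SDs ([clnm_reference_summaries()]) and the
#' nodule-level categorical sonographic variables at the published per-group
#' proportions ([clnm_reference_counts()]). The two patient-level tables (sex
#' and the 55-year age split, tabulated over 68/102 patients) are not
#' simulated at nodule level because their counts do not apply to the 74/108
#' split; continuous age is simulated from its printed means and SDs.
#'
#' @param n_pos,n_neg Group sizes (defaults: the study's 74 and 108).
#' @return A [cohort_params()] object.
#' @export
#' @examples
#' cohort <- simulate_cohort(reference_cohort_params(), seed = 1)
#' table(cohort$clnm)
reference_cohort_params <- function(n_pos = 74L, n_neg = 108L) {
  counts <- clnm_reference_counts()
  counts$sex <- NULL
  counts$age_ge55 <- NULL
  if (n_pos != 74L || n_neg != 108L) {
    # rescale printed counts to the requested group sizes (proportions kept)
    counts <- lapply(counts, function(spec) {
      spec$counts_pos <- round_counts(spec$counts_pos, n_pos)
      spec$counts_neg <- round_counts(spec$counts_neg, n_neg)
      spec
    })
  }
  cohort_params(n_pos = n_pos, n_neg = n_neg,
                continuous = clnm_reference_summaries()[, 1:5],
                categorical = unname(counts))
}

# largest-remainder rescaling of a count vector to a new total
round_counts <- function(counts, total) {
  if (sum(counts) == 0) return(rep(0L, length(counts)))
  raw <- counts / sum(counts) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Expand a two-group contingency specification to per-record codes
#'
#' Reconstructs the record-level data behind a printed contingency table:
#' one row per observation with the 0-based ordinal level code and the binary
#' group label. Useful for computing rank statistics (e.g. the ROC AUC of an
#' ordinal predictor) directly from published counts.
#'
#' @param spec One element of [clnm_reference_counts()] (fields `levels`,
#'   `counts_pos`, `counts_neg`).
#' @return Data.frame with columns `code` (integer) and `label`
#'   (1 = positive group).
#' @export
#' @examples
#' foci <- expand_counts(clnm_reference_counts()$echogenic_foci_code)
#' nrow(foci)  # 182 nodules
expand_counts <- function(spec) {
  k <- length(spec$levels)
  data.frame(
    code = c(rep(0:(k - 1), spec$counts_pos), rep(0:(k - 1), spec$counts_neg)),
    label = rep(c(1L, 0L), c(sum(spec$counts_pos), sum(spec$counts_neg))))
}
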