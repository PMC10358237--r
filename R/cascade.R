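#' Three-stage association cascade
#'
#' Runs the study's full statistical pipeline on a nodule-level cohort table
#' with a binary `clnm` label:
#' \enumerate{
#'   \item Univariate screening — pooled t test for every continuous
#'     variable, Pearson chi-square (no continuity correction) on the
#'     level-by-group contingency table for every categorical variable.
#'   \item ROC analysis for every stage-1 variable with `p < alpha`
#'     (default 0.05). Categorical variables enter as their ordinal integer
#'     codes; the orientation is fixed (higher value indicates CLNM) and
#'     AUCs below 0.5 are reported untouched.
#'   \item One multiple linear regression of the outcome code on all stage-2
#'     variables with `AUC > auc_gate` (default 0.50), reporting
#'     unstandardized and standardized coefficients.
#' }
#' Empty stage-2 or stage-3 sets are reported, not an error. The cascade is a
#' pure function of its input table: it draws no random numbers.
#'
#' @param cohort Data.frame with a `clnm` column (1 = CLNM positive) and the
#'   feature columns.
#' @param continuous,categorical Character vectors naming the columns to
#'   screen. Defaults: the reference-study variable inventory
#'   ([clnm_reference_summaries()] names and the nodule-level categorical
#'   codes) intersected with the columns present.
#' @param alpha Stage-1 significance gate (default 0.05).
#' @param auc_gate Stage-2 AUC gate (default 0.50, strict inequality).
#' @param outcome_codes Numeric codes for (negative, positive) used as the
#'   regression outcome; default `c(1, 2)`. Standardized betas are invariant
#'   (up to sign) to this choice.
#' @return An `association_report` list: `univariate` (data.frame),
#'   `roc` (data.frame plus `roc_detail`, the full `roc_result`s),
#'   `regression` (a `regression_result` or NULL), and the gates used.
#' @export
#' @examples
#' cohort <- simulate_cohort(reference_cohort_params(), seed = 1)
#' rep <- run_association_cascade(cohort)
#' rep$roc
run_association_cascade <- function(cohort,
                                    continuous = NULL, categorical = NULL,
                                    alpha = 0.05, auc_gate = 0.50,
                                    outcome_codes = c(1, 2)) {
  stopifnot("clnm" %in% names(cohort))
  lab <- as.integer(cohort$clnm)
  if (!all(lab %in% c(0L, 1L))) stop("clnm must be coded 0/1")
  if (is.null(continuous))
    continuous <- intersect(clnm_reference_summaries()$name, names(cohort))
  if (is.null(categorical))
    categorical <- intersect(
      setdiff(names(clnm_reference_counts()), c("sex", "age_ge55")),
      names(cohort))

  uni <- list()
  for (v in continuous) {
    cmp <- pooled_t_test(cohort[[v]][lab == 1L], cohort[[v]][lab == 0L])
    uni[[v]] <- data.frame(variable = v, type = "continuous", test = "pooled_t",
                           statistic = cmp$statistic, df = cmp$df,
                           p_value = cmp$p_value, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    counts <- as.matrix(table(factor(cohort[[v]]), factor(lab, levels = c(1, 0))))
    cmp <- suppressWarnings(pearson_chi2(counts))
    uni[[v]] <- data.frame(variable = v, type = "categorical",
                           test = "pearson_chi2", statistic = cmp$statistic,
                           df = cmp$df, p_value = cmp$p_value,
                           stringsAsFactors = FALSE)
  }
  univariate <- do.call(rbind, c(uni, list(make.row.names = FALSE)))

  stage2_vars <- univariate$variable[univariate$p_value < alpha]
  roc_detail <- lapply(stage2_vars, function(v) roc_auc(cohort[[v]], lab))
  names(roc_detail) <- stage2_vars
  roc_tab <- if (length(stage2_vars)) do.call(rbind, lapply(stage2_vars, function(v) {
    r <- roc_detail[[v]]
    data.frame(variable = v, auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high,
               p_value = r$p_value, threshold = r$threshold,
               sensitivity = r$sensitivity, specificity = r$specificity,
               stringsAsFactors = FALSE)
  })) else data.frame(variable = character(), auc = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p_value = numeric(), threshold = numeric(),
                      sensitivity = numeric(), specificity = numeric())

  stage3_vars <- roc_tab$variable[roc_tab$auc > auc_gate]
  regression <- NULL
  if (length(stage3_vars)) {
    y <- ifelse(lab == 1L, outcome_codes[2], outcome_codes[1])
    regression <- linear_regression_standardized(
      y, cohort[, stage3_vars, drop = FALSE])
  }
  structure(list(univariate = univariate, roc = roc_tab,
                 roc_detail = roc_detail, regression = regression,
                 stage2_vars = stage2_vars, stage3_vars = stage3_vars,
                 alpha = alpha, auc_gate = auc_gate),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat(sprintf("Association cascade: %d variables screened, %d with p < %.2g, %d with AUC > %.2g\n",
              nrow(x$univariate), length(x$stage2_vars), x$alpha,
              length(x$stage3_vars), x$auc_gate))
  if (!is.null(x$regression)) {
    cat("Regression terms:\n")
    print.data.frame(x$regression, digits = 3)
  }
  invisible(x)
}

#' Write an association report to disk
#'
#' Emits the three stage tables as CSVs (`univariate.csv`, `roc.csv`,
#' `regression.csv`) mirroring the published tables' column structure, and
#' the full report (including all ROC coordinates) as `report.json`.
#'
#' @param report An `association_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_association_report <- function(report, dir) {
  stopifnot(inherits(report, "association_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(file.path(dir, "univariate.csv"), file.path(dir, "roc.csv"),
             file.path(dir, "regression.csv"), file.path(dir, "report.json"))
  write.csv(report$univariate, paths[1], row.names = FALSE)
  write.csv(report$roc, paths[2], row.names = FALSE)
  if (!is.null(report$regression)) {
    write.csv(as.data.frame(report$regression), paths[3], row.names = FALSE)
  } else write.csv(data.frame(), paths[3], row.names = FALSE)
  json <- list(
    univariate = report$univariate, roc = report$roc,
    regression = if (is.null(report$regression)) NULL else
      as.data.frame(report$regression),
    roc_coordinates = lapply(report$roc_detail, function(r) r$coordinates),
    alpha = report$alpha, auc_gate = report$auc_gate)
  jsonlite::write_json(json, paths[4], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
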