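#' Two-group cohort simulation parameters
#'
#' Bundles the group sizes and per-variable sampling specifications for a
#' synthetic nodule-level cohort with a binary CLNM label. Continuous
#' variables are drawn from per-group normal distributions; categorical
#' variables are drawn multinomially with per-level probabilities equal to
#' the specified per-group counts divided by the group size.
#'
#' @param n_pos,n_neg Nodules in the CLNM-positive / negative group.
#' @param continuous Data frame with columns `name`, `mean_pos`, `sd_pos`,
#'   `mean_neg`, `sd_neg` (one row per variable; SDs > 0).
#' @param categorical List of specs, each a list with `name`, `levels`
#'   (ordered labels; the integer code of a level is its 0-based position),
#'   `counts_pos`, `counts_neg` (per-level counts summing to the group size).
#' @return An object of class `cohort_params`.
#' @seealso [reference_cohort_params()] for the defaults that emulate the
#'   published PTC/CLNM study cohort.
#' @export
cohort_params <- function(n_pos, n_neg, continuous = NULL, categorical = NULL) {
  n_pos <- as.integer(n_pos); n_neg <- as.integer(n_neg)
  if (is.na(n_pos) || is.na(n_neg) || n_pos < 0L || n_neg < 0L)
    stop("group sizes must be nonnegative integers")
  if (!is.null(continuous)) {
    stopifnot(all(c("name", "mean_pos", "sd_pos", "mean_neg", "sd_neg") %in%
                    names(continuous)))
    if (any(continuous$sd_pos <= 0) || any(continuous$sd_neg <= 0))
      stop("continuous SDs must be > 0")
  }
  for (spec in categorical) {
    stopifnot(all(c("name", "levels", "counts_pos", "counts_neg") %in% names(spec)))
    k <- length(spec$levels)
    if (length(spec$counts_pos) != k || length(spec$counts_neg) != k)
      stop("count vectors must match the number of levels for ", spec$name)
    if (any(spec$counts_pos < 0) || any(spec$counts_neg < 0))
      stop("negative category count for ", spec$name)
    if (n_pos > 0 && sum(spec$counts_pos) != n_pos)
      stop("positive-group counts for ", spec$name, " must sum to n_pos")
    if (n_neg > 0 && sum(spec$counts_neg) != n_neg)
      stop("negative-group counts for ", spec$name, " must sum to n_neg")
  }
  structure(list(n_pos = n_pos, n_neg = n_neg,
                 continuous = continuous, categorical = categorical),
            class = "cohort_params")
}

#' Simulate a nodule-level two-group cohort
#'
#' Draws `n_pos + n_neg` nodule records. The CLNM label is 1 for the positive
#' group and 0 for the negative group. Continuous variables are independent
#' normals with the group-specific mean and SD; categorical variables are
#' independent multinomials with per-level probabilities `counts / group n`,
#' stored as 0-based integer codes in level order (ordinal coding). When the
#' parameter set contains a `max_diameter_mm` variable, plausible caliper
#' columns (`length_mm`, `height_mm`, `width_mm`, `volume_mm3`, `ar_cross`,
#' `ar_long`) are generated around it: the drawn diameter is assigned to the
#' nodule length and height/width are uniform fractions of it, so
#' `max_diameter_mm` keeps exactly its specified group distribution.
#'
#' @param params A [cohort_params()].
#' @param seed Integer seed; the draw is deterministic given `params` and
#'   `seed`.
#' @return A data.frame with one row per nodule: `nodule_id`, `clnm`, one
#'   column per specified variable, and the derived caliper columns when
#'   applicable. The categorical level labels are attached as attribute
#'   `level_labels` (a named list).
#' @export
simulate_cohort <- function(params, seed = 1L) {
  stopifnot(inherits(params, "cohort_params"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(derive_seed(seed, 0L))
  n <- params$n_pos + params$n_neg
  clnm <- rep(c(1L, 0L), c(params$n_pos, params$n_neg))
  out <- data.frame(nodule_id = sprintf("N%03d", seq_len(n)), clnm = clnm,
                    stringsAsFactors = FALSE)
  cont <- params$continuous
  if (!is.null(cont)) for (i in seq_len(nrow(cont))) {
    v <- numeric(n)
    v[clnm == 1L] <- rnorm(params$n_pos, cont$mean_pos[i], cont$sd_pos[i])
    v[clnm == 0L] <- rnorm(params$n_neg, cont$mean_neg[i], cont$sd_neg[i])
    out[[cont$name[i]]] <- v
  }
  labels <- list()
  for (spec in params$categorical) {
    k <- length(spec$levels)
    v <- integer(n)
    if (params$n_pos > 0)
      v[clnm == 1L] <- sample.int(k, params$n_pos, replace = TRUE,
                                  prob = spec$counts_pos / params$n_pos) - 1L
    if (params$n_neg > 0)
      v[clnm == 0L] <- sample.int(k, params$n_neg, replace = TRUE,
                                  prob = spec$counts_neg / params$n_neg) - 1L
    out[[spec$name]] <- v
    labels[[spec$name]] <- spec$levels
  }
  if ("max_diameter_mm" %in% names(out)) {
    d <- pmax(out$max_diameter_mm, 1)  # calipers cannot be <= 0
    out$max_diameter_mm <- d
    out$length_mm <- d
    out$height_mm <- runif(n, 0.5, 0.95) * d
    out$width_mm <- runif(n, 0.55, 1.0) * d
    out$volume_mm3 <- nodule_volume(out$length_mm, out$height_mm, out$width_mm)
    ar <- aspect_ratios(out$length_mm, out$height_mm, out$width_mm)
    out$ar_cross <- ar[seq_len(n)]
    out$ar_long <- ar[n + seq_len(n)]
  }
  attr(out, "level_labels") <- labels
  out
}
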