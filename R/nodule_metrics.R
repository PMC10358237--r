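#' Nodule caliper metrics
#'
#' The three recorded diameters of a thyroid nodule are: `length`, the longest
#' diameter on the largest longitudinal section; `height`, its perpendicular
#' on the same section; and `width`, the largest left-right diameter on the
#' transverse section. From these, the ellipsoid-style volume is
#' `0.523 * length * height * width` (mm^3), the cross-sectional aspect ratio
#' is `height / width`, the longitudinal aspect ratio is `height / length`,
#' and the maximum diameter is the largest of the three.
#'
#' @param length_mm,height_mm,width_mm Nodule diameters in mm, each positive
#'   and at most 200 mm (plausibility bound).
#' @return `nodule_volume()`: volume in mm^3. `aspect_ratios()`: named vector
#'   `c(cross_sectional, longitudinal)`. `max_diameter()`: mm.
#' @export
#' @examples
#' nodule_volume(13.2, 13.5, 14.1)   # 1314.1 mm^3
#' aspect_ratios(7.4, 6.1, 6.5)      # 0.938, 0.824
nodule_volume <- function(length_mm, height_mm, width_mm) {
  check_dims(length_mm, height_mm, width_mm)
  0.523 * length_mm * height_mm * width_mm
}

#' @rdname nodule_volume
#' @export
aspect_ratios <- function(length_mm, height_mm, width_mm) {
  check_dims(length_mm, height_mm, width_mm)
  c(cross_sectional = height_mm / width_mm, longitudinal = height_mm / length_mm)
}

#' @rdname nodule_volume
#' @export
max_diameter <- function(length_mm, height_mm, width_mm) {
  check_dims(length_mm, height_mm, width_mm)
  pmax(length_mm, height_mm, width_mm)
}

check_dims <- function(length_mm, height_mm, width_mm) {
  d <- c(length_mm, height_mm, width_mm)
  if (any(!is.finite(d)) || any(d <= 0)) stop("nodule dimensions must be positive")
  if (any(d > 200)) stop("nodule dimension exceeds the 200 mm plausibility bound")
  invisible(TRUE)
}

#' Reconcile two readers' measurements
#'
#' Two sonographers measure independently; if their values agree to within
#' the tolerance (inclusive at exactly the tolerance, default 2 mm) the
#' average is recorded, otherwise the measurement is flagged for senior-reader
#' adjudication.
#'
#' @param a,b The two readings (mm), both positive.
#' @param tolerance_mm Maximum allowed absolute disagreement (default 2).
#' @return The averaged value, or `NA` with attribute
#'   `adjudication_required = TRUE` when the readings disagree beyond
#'   tolerance.
#' @export
#' @examples
#' reconcile_measurements(10, 11)   # 10.5
#' reconcile_measurements(10, 13)   # NA, flagged
reconcile_measurements <- function(a, b, tolerance_mm = 2) {
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop("measurements must be positive")
  if (abs(a - b) <= tolerance_mm) return((a + b) / 2)
  structure(NA_real_, adjudication_required = TRUE)
}
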