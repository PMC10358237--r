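#' Eight spectral features of one ROI on one frame
#'
#' Computes the full quantitative parameter set for a single rectangular ROI:
#' Higuchi fractal dimension of the raw RF lines ([roi_higuchi()]), then the
#' straight-line fit (slope, intercept, mid-band) and the sub-band means
#' S1-S4 of the max-normalized mean power spectrum.
#'
#' @param frame An `rf_frame` matrix.
#' @param roi An [roi_spec()].
#' @param n_fft,window,power Passed to [roi_power_spectrum()].
#' @param band Fit band for [fit_spectral_line()].
#' @param k_max Passed to [roi_higuchi()].
#' @return Named numeric vector `higuchi, slope, intercept, mid_band,
#'   s1, s2, s3, s4`.
#' @export
extract_roi_features <- function(frame, roi, n_fft = NULL,
                                 window = c("hann", "rectangular"),
                                 power = FALSE, band = c(0, 0.5), k_max = 8L) {
  window <- match.arg(window)
  spec <- normalize_spectrum(
    roi_power_spectrum(frame, roi, n_fft = n_fft, window = window, power = power))
  fit <- fit_spectral_line(spec, band = band)
  s <- band_means(spec)
  c(higuchi = roi_higuchi(frame, roi, k_max = k_max),
    slope = fit$slope, intercept = fit$intercept, mid_band = fit$mid_band, s)
}

#' Case-level feature extraction with frame and reader averaging
#'
#' Implements the clinical reading protocol: for each section, a typical
#' frame and the frames immediately before and after it are analyzed; the
#' eight parameters are computed on each of the three frames and averaged
#' parameterwise; then the two readers' results (each reader outlines their
#' own ROI) are averaged parameterwise to give the recorded value.
#'
#' @param case A `case_recording` from [simulate_case()] or
#'   [read_rf_container()] (list of sections of frames).
#' @param rois Named list per section (`transverse`, `longitudinal`), each a
#'   list of one [roi_spec()] per reader. A single `roi_spec` is accepted and
#'   treated as both readers agreeing. Defaults to the case's own nodule ROI.
#' @param typical_frame 1-based index of the typical frame; must be interior
#'   (`2 <= typical_frame <= n_frames - 1`) so that its neighbours exist.
#' @param ... Passed to [extract_roi_features()].
#' @return A data.frame with one row per section and columns `section`,
#'   `higuchi`, `slope`, `intercept`, `mid_band`, `s1`..`s4`.
#' @export
extract_case_features <- function(case, rois = NULL,
                                  typical_frame = NULL, ...) {
  sections <- case$sections
  stopifnot(is.list(sections), all(c("transverse", "longitudinal") %in% names(sections)))
  n_frames <- length(sections[[1]])
  if (is.null(typical_frame)) typical_frame <- (n_frames + 1L) %/% 2L
  if (typical_frame < 2L || typical_frame > n_frames - 1L)
    stop("typical_frame must be interior: 2 <= t <= n_frames - 1")
  if (is.null(rois)) rois <- list(transverse = case$roi, longitudinal = case$roi)
  rows <- lapply(c("transverse", "longitudinal"), function(sec) {
    reader_rois <- rois[[sec]]
    if (is.null(reader_rois)) stop("missing reader ROI for section ", sec)
    if (inherits(reader_rois, "roi_spec")) reader_rois <- list(reader_rois, reader_rois)
    per_reader <- lapply(reader_rois, function(roi) {
      per_frame <- vapply(
        (typical_frame - 1L):(typical_frame + 1L),
        function(f) extract_roi_features(sections[[sec]][[f]], roi, ...),
        numeric(8))
      rowMeans(per_frame)
    })
    feats <- rowMeans(do.call(cbind, per_reader))
    cbind(data.frame(section = sec, stringsAsFactors = FALSE),
          as.data.frame(as.list(feats)))
  })
  do.call(rbind, rows)
}
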