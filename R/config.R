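#' Acquisition configuration for RF frame simulation
#'
#' Describes the pulse-echo acquisition geometry and timing. Defaults follow
#' the clinical acquisition protocol the package emulates: second-harmonic
#' imaging with a 5 MHz transmit / 10 MHz receive pair, 50 MHz sampling,
#' 312 scan lines per frame and 20 frames per case. The number of samples per
#' line is an implementation choice (2048, so that a nodule-sized ROI spans at
#' least 256 depth samples at 50 MHz).
#'
#' @param sampling_rate_hz Sampling rate of the RF digitizer (Hz).
#' @param lines_per_frame Number of scan lines (A-lines) per frame.
#' @param samples_per_line Depth samples per scan line.
#' @param n_frames Frames acquired per section of a case.
#' @param tx_frequency_hz Transmit center frequency (Hz). Recorded as
#'   metadata; echoes are generated directly in the receive band.
#' @param rx_center_frequency_hz Receive (second-harmonic) center frequency
#'   (Hz); the simulated pulse is centered here.
#' @param pulse_bandwidth_fraction -6 dB fractional bandwidth of the receive
#'   pulse (dimensionless).
#' @return An object of class `acquisition_config`.
#' @export
#' @examples
#' acq <- acquisition_config()
#' acq$rx_center_frequency_hz / acq$sampling_rate_hz  # 0.2 cycles/sample
acquisition_config <- function(sampling_rate_hz = 5e7,
                               lines_per_frame = 312L,
                               samples_per_line = 2048L,
                               n_frames = 20L,
                               tx_frequency_hz = 5e6,
                               rx_center_frequency_hz = 1e7,
                               pulse_bandwidth_fraction = 0.6) {
  cfg <- list(
    sampling_rate_hz = as.numeric(sampling_rate_hz),
    lines_per_frame = as.integer(lines_per_frame),
    samples_per_line = as.integer(samples_per_line),
    n_frames = as.integer(n_frames),
    tx_frequency_hz = as.numeric(tx_frequency_hz),
    rx_center_frequency_hz = as.numeric(rx_center_frequency_hz),
    pulse_bandwidth_fraction = as.numeric(pulse_bandwidth_fraction)
  )
  counts <- c(cfg$lines_per_frame, cfg$samples_per_line, cfg$n_frames)
  if (any(is.na(counts)) || any(counts < 1L))
    stop("lines_per_frame, samples_per_line and n_frames must all be >= 1")
  if (!(cfg$sampling_rate_hz > 2 * cfg$rx_center_frequency_hz))
    stop("sampling_rate_hz must exceed twice rx_center_frequency_hz (Nyquist)")
  if (cfg$pulse_bandwidth_fraction < 0)
    stop("pulse_bandwidth_fraction must be >= 0")
  structure(cfg, class = "acquisition_config")
}

#' Scatterer phantom configuration
#'
#' The phantom is a 1-D per-line scatterer field: each scan line carries a
#' random impulse train (Poisson number of scatterers at uniform depths, with
#' zero-mean Gaussian amplitudes) which is convolved with the receive pulse,
#' attenuated with depth, and corrupted with white Gaussian electronic noise.
#' An optional rectangular nodule region overrides the scatterer density and
#' amplitude inside it, emulating a lesion with different microstructure.
#'
#' @param scatterer_density Expected scatterers per depth sample (>= 0).
#' @param amplitude_sd Standard deviation of scatterer reflectivity.
#' @param attenuation_db_per_cm_mhz Attenuation coefficient (dB/cm/MHz),
#'   applied at the receive center frequency over the two-way path.
#' @param noise_sd Standard deviation of additive white electronic noise.
#' @param speed_of_sound_m_s Speed of sound used to convert sample depth to
#'   distance (m/s).
#' @param nodule_region Optional [roi_spec()] giving the nodule rectangle, or
#'   `NULL` for a homogeneous phantom.
#' @param nodule_density,nodule_amplitude_sd Scatterer density and amplitude
#'   SD inside `nodule_region` (default: same as background).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(scatterer_density = 0.05,
                           amplitude_sd = 1,
                           attenuation_db_per_cm_mhz = 0.5,
                           noise_sd = 0.02,
                           speed_of_sound_m_s = 1540,
                           nodule_region = NULL,
                           nodule_density = scatterer_density,
                           nodule_amplitude_sd = amplitude_sd) {
  if (scatterer_density < 0 || nodule_density < 0)
    stop("scatterer densities must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (amplitude_sd < 0 || nodule_amplitude_sd < 0)
    stop("amplitude SDs must be >= 0")
  if (!is.null(nodule_region) && !inherits(nodule_region, "roi_spec"))
    stop("nodule_region must be an roi_spec or NULL")
  structure(list(
    scatterer_density = scatterer_density,
    amplitude_sd = amplitude_sd,
    attenuation_db_per_cm_mhz = attenuation_db_per_cm_mhz,
    noise_sd = noise_sd,
    speed_of_sound_m_s = speed_of_sound_m_s,
    nodule_region = nodule_region,
    nodule_density = nodule_density,
    nodule_amplitude_sd = nodule_amplitude_sd
  ), class = "phantom_config")
}

#' Rectangular region of interest on an RF frame
#'
#' Coordinates are 0-based, half-open intervals in (line, sample) order, so
#' `line_start = 0, line_stop = 10` selects the first ten scan lines. The ROI
#' must span at least 16 depth samples so that a spectrum can be estimated.
#'
#' @param line_start,line_stop Scan-line interval, 0-based half-open.
#' @param sample_start,sample_stop Depth-sample interval, 0-based half-open.
#' @return An object of class `roi_spec`.
#' @export
#' @examples
#' roi_spec(10, 50, 200, 712)
roi_spec <- function(line_start, line_stop, sample_start, sample_stop) {
  v <- c(line_start, line_stop, sample_start, sample_stop)
  if (any(is.na(v)) || any(v != floor(v))) stop("ROI coordinates must be integers")
  if (line_start < 0 || line_start >= line_stop)
    stop("need 0 <= line_start < line_stop")
  if (sample_start < 0 || sample_start >= sample_stop)
    stop("need 0 <= sample_start < sample_stop")
  if (sample_stop - sample_start < 16)
    stop("ROI must span at least 16 depth samples")
  structure(list(
    line_start = as.integer(line_start), line_stop = as.integer(line_stop),
    sample_start = as.integer(sample_start), sample_stop = as.integer(sample_stop)
  ), class = "roi_spec")
}

# check an ROI fits inside a [lines x samples] frame; stop with context if not
validate_roi <- function(roi, n_lines, n_samples) {
  stopifnot(inherits(roi, "roi_spec"))
  if (roi$line_stop > n_lines || roi$sample_stop > n_samples)
    stop(sprintf(
      "ROI [%d,%d) x [%d,%d) exceeds frame extent %d lines x %d samples",
      roi$line_start, roi$line_stop, roi$sample_start, roi$sample_stop,
      n_lines, n_samples))
  invisible(roi)
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "RF acquisition: %.0f MHz sampling, %d lines x %d samples, %d frames, rx %.1f MHz (bw %.0f%%)\n",
    x$sampling_rate_hz / 1e6, x$lines_per_frame, x$samples_per_line,
    x$n_frames, x$rx_center_frequency_hz / 1e6, 100 * x$pulse_bandwidth_fraction))
  invisible(x)
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("ROI lines [%d,%d) x samples [%d,%d)\n",
              x$line_start, x$line_stop, x$sample_start, x$sample_stop))
  invisible(x)
}
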