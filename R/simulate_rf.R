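#' Gaussian-modulated receive pulse
#'
#' Builds the impulse response used by the phantom simulator: a cosine at the
#' receive center frequency under a Gaussian envelope whose -6 dB fractional
#' bandwidth equals `pulse_bandwidth_fraction`, sampled at the acquisition
#' rate, unit peak amplitude, truncated where the envelope falls below 1e-3 of
#' its peak. A zero bandwidth fraction degenerates to a pure (untruncatable)
#' tone, so a minimal nonzero envelope width is enforced only through the
#' truncation rule.
#'
#' @param acq An [acquisition_config()].
#' @return Numeric vector of pulse samples (odd length, symmetric envelope).
#' @export
#' @examples
#' p <- make_pulse(acquisition_config())
#' max(abs(p))  # 1
make_pulse <- function(acq) {
  stopifnot(inherits(acq, "acquisition_config"))
  fs <- acq$sampling_rate_hz
  fc <- acq$rx_center_frequency_hz
  bw <- acq$pulse_bandwidth_fraction
  if (bw <= 0) stop("pulse_bandwidth_fraction must be > 0 to truncate the pulse")
  # Gaussian envelope exp(-a t^2) with -6 dB (amplitude ratio 10^(-6/20))
  # fractional bandwidth bw of the magnitude spectrum.
  ref <- 10^(-6 / 20)
  a <- -(pi * fc * bw)^2 / (4 * log(ref))
  t_max <- sqrt(log(1e3) / a)
  n_half <- ceiling(t_max * fs)
  t <- seq(-n_half, n_half) / fs
  exp(-a * t^2) * cos(2 * pi * fc * t)
}

# deterministic child-seed derivation from one master seed (kept < 2^31)
derive_seed <- function(master, index) {
  as.integer((abs(as.numeric(master)) * 48271 + as.numeric(index) * 7919 + 1) %%
               2147483629)
}

# depth-dependent amplitude attenuation profile for one line
attenuation_profile <- function(phantom, acq) {
  n <- acq$samples_per_line
  depth_cm <- (seq_len(n) - 1) / acq$sampling_rate_hz *
    phantom$speed_of_sound_m_s / 2 * 100
  f_mhz <- acq$rx_center_frequency_hz / 1e6
  # two-way path: 2 x depth
  10^(-(phantom$attenuation_db_per_cm_mhz * f_mhz * 2 * depth_cm) / 20)
}

# impulse train for one line: scatterer positions/amplitudes -> sample vector
scatterer_train <- function(n_samples, density, amp_sd, in_nodule = NULL,
                            nodule_density = density, nodule_amp_sd = amp_sd) {
  train <- numeric(n_samples)
  place <- function(n_scat, lo, hi, sd) {
    if (n_scat == 0L) return(invisible(NULL))
    pos <- floor(runif(n_scat, lo, hi)) + 1L  # 1-based sample index
    amp <- rnorm(n_scat, 0, sd)
    for (j in seq_len(n_scat)) train[pos[j]] <<- train[pos[j]] + amp[j]
    invisible(NULL)
  }
  place(rpois(1L, density * n_samples), 0, n_samples, amp_sd)
  if (!is.null(in_nodule)) {
    extent <- in_nodule[2] - in_nodule[1]
    place(rpois(1L, nodule_density * extent), in_nodule[1], in_nodule[2],
          nodule_amp_sd)
  }
  train
}

# convolve impulse train with pulse, pulse center aligned on scatterer position
convolve_pulse <- function(train, pulse) {
  n <- length(train)
  np <- length(pulse)
  m <- n + np - 1L
  nfft <- 2^ceiling(log2(m))
  full <- Re(fft(fft(c(train, numeric(nfft - n))) *
                 fft(c(pulse, numeric(nfft - np))), inverse = TRUE)) / nfft
  offset <- (np - 1L) %/% 2L
  full[(offset + 1L):(offset + n)]
}

#' Simulate one RF frame from a scatterer phantom
#'
#' Per scan line, draws a Poisson number of point scatterers at uniform depth
#' positions with zero-mean Gaussian reflectivities, convolves the impulse
#' train with the receive pulse ([make_pulse()]), applies a depth-dependent
#' exponential attenuation at the receive center frequency, and adds white
#' Gaussian noise. Inside `phantom$nodule_region` (if set) additional
#' scatterers are drawn with the nodule's own density and amplitude, so lesion
#' and background microstructure can differ. Deterministic for a fixed seed.
#'
#' @param phantom A [phantom_config()].
#' @param acq An [acquisition_config()].
#' @param seed Integer seed; all randomness in the frame flows from it.
#' @return An `rf_frame`: a numeric matrix `[lines x samples]` with the
#'   acquisition config attached as attribute `acq`.
#' @export
simulate_rf_frame <- function(phantom, acq, seed) {
  stopifnot(inherits(phantom, "phantom_config"), inherits(acq, "acquisition_config"))
  if (!is.null(phantom$nodule_region))
    validate_roi(phantom$nodule_region, acq$lines_per_frame, acq$samples_per_line)
  frame <- simulate_scatter_frame(phantom, acq, seed)
  if (phantom$noise_sd > 0)
    frame <- add_frame_noise(frame, phantom$noise_sd, derive_seed(seed, 7L))
  frame
}

# noiseless scattering component of a frame (shared across frames of a case)
simulate_scatter_frame <- function(phantom, acq, seed) {
  pulse <- make_pulse(acq)
  atten <- attenuation_profile(phantom, acq)
  nl <- acq$lines_per_frame
  ns <- acq$samples_per_line
  roi <- phantom$nodule_region
  frame <- matrix(0, nrow = nl, ncol = ns)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  for (i in seq_len(nl)) {
    set.seed(derive_seed(seed, i))
    in_nodule <- NULL
    if (!is.null(roi) && (i - 1L) >= roi$line_start && (i - 1L) < roi$line_stop)
      in_nodule <- c(roi$sample_start, roi$sample_stop)
    train <- scatterer_train(ns, phantom$scatterer_density, phantom$amplitude_sd,
                             in_nodule, phantom$nodule_density,
                             phantom$nodule_amplitude_sd)
    if (any(train != 0)) frame[i, ] <- convolve_pulse(train, pulse) * atten
  }
  structure(frame, acq = acq, class = c("rf_frame", "matrix", "array"))
}

add_frame_noise <- function(frame, noise_sd, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(seed)
  frame + matrix(rnorm(length(frame), 0, noise_sd), nrow = nrow(frame))
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a full case recording (two sections, repeated frames)
#'
#' A case is imaged in two orthogonal sections (transverse and longitudinal).
#' Within a section all frames share one realization of the scatterer field —
#' the tissue does not change between frames — and differ only by independent
#' electronic-noise draws; the two sections use independent scatterer fields.
#' Each frame carries the nodule ROI, mirroring how a sonographer outlines the
#' lesion on every analyzed frame.
#'
#' @inheritParams simulate_rf_frame
#' @return A `case_recording`: list with `sections`, a named list
#'   (`transverse`, `longitudinal`) of lists of `rf_frame`s, the `roi`
#'   (nodule region, or full-frame ROI if the phantom has none), `acq`, and
#'   the master `seed`.
#' @export
simulate_case <- function(phantom, acq, seed) {
  stopifnot(inherits(phantom, "phantom_config"), inherits(acq, "acquisition_config"))
  if (!is.null(phantom$nodule_region))
    validate_roi(phantom$nodule_region, acq$lines_per_frame, acq$samples_per_line)
  roi <- phantom$nodule_region
  if (is.null(roi))
    roi <- roi_spec(0, acq$lines_per_frame, 0, acq$samples_per_line)
  sections <- list()
  for (s in seq_along(c("transverse", "longitudinal"))) {
    base_seed <- derive_seed(seed, 1000L * s)
    scatter <- simulate_scatter_frame(phantom, acq, base_seed)
    frames <- vector("list", acq$n_frames)
    for (f in seq_len(acq$n_frames)) {
      frames[[f]] <- if (phantom$noise_sd > 0) {
        add_frame_noise(scatter, phantom$noise_sd, derive_seed(base_seed, 5000L + f))
      } else scatter
    }
    sections[[s]] <- frames
  }
  names(sections) <- c("transverse", "longitudinal")
  structure(list(sections = sections, roi = roi, acq = acq, seed = seed),
            class = "case_recording")
}

#' @export
print.case_recording <- function(x, ...) {
  cat(sprintf("RF case recording: 2 sections x %d frames of %d lines x %d samples (seed %s)\n",
              x$acq$n_frames, x$acq$lines_per_frame, x$acq$samples_per_line,
              format(x$seed)))
  invisible(x)
}
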