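#' Binary RF frame container
#'
#' No standard interchange format exists for raw ultrasound RF frames, so the
#' package defines one: a directory holding `meta.json` (acquisition
#' metadata) and `frames.bin`, little-endian 32-bit floats in
#' `[frame][line][sample]` order. Required metadata keys: `sampling_rate_hz`,
#' `lines_per_frame`, `samples_per_line`, `n_frames`, `tx_frequency_hz`,
#' `rx_center_frequency_hz`, `section`, `dtype` (`"float32"`) and
#' `byte_order` (`"little"`). The reader validates the byte count against the
#' declared geometry.
#'
#' @param frames List of `rf_frame` matrices (`[lines x samples]`), all of
#'   identical dimensions.
#' @param path Container directory (created by the writer).
#' @param acq The [acquisition_config()] the frames were generated under.
#' @param section `"transverse"` or `"longitudinal"`.
#' @return `write_rf_container()`: the path, invisibly.
#'   `read_rf_container()`: list with `frames` (list of matrices) and `meta`.
#' @export
write_rf_container <- function(frames, path, acq, section = "transverse") {
  stopifnot(is.list(frames), length(frames) >= 1)
  nl <- nrow(frames[[1]]); ns <- ncol(frames[[1]])
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(sampling_rate_hz = acq$sampling_rate_hz,
               lines_per_frame = nl, samples_per_line = ns,
               n_frames = length(frames),
               tx_frequency_hz = acq$tx_frequency_hz,
               rx_center_frequency_hz = acq$rx_center_frequency_hz,
               section = section, dtype = "float32", byte_order = "little")
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(file.path(path, "frames.bin"), "wb")
  on.exit(close(con))
  for (fr in frames) {
    stopifnot(nrow(fr) == nl, ncol(fr) == ns)
    # row-major: each line's samples contiguous
    writeBin(as.numeric(t(fr)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_rf_container
#' @export
read_rf_container <- function(path) {
  meta_path <- file.path(path, "meta.json")
  bin_path <- file.path(path, "frames.bin")
  if (!file.exists(meta_path)) stop("rf_container_error: missing meta.json in ", path)
  if (!file.exists(bin_path)) stop("rf_container_error: missing frames.bin in ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  required <- c("sampling_rate_hz", "lines_per_frame", "samples_per_line",
                "n_frames", "tx_frequency_hz", "rx_center_frequency_hz",
                "section", "dtype", "byte_order")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("rf_container_schema_error: missing metadata key(s): ",
         paste(missing, collapse = ", "))
  if (!identical(meta$dtype, "float32"))
    stop("rf_container_dtype_error: unsupported dtype '", meta$dtype, "'")
  if (!identical(meta$byte_order, "little"))
    stop("rf_container_dtype_error: unsupported byte order '", meta$byte_order, "'")
  nl <- meta$lines_per_frame; ns <- meta$samples_per_line; nf <- meta$n_frames
  expected_bytes <- as.numeric(nf) * nl * ns * 4
  actual_bytes <- file.size(bin_path)
  if (actual_bytes != expected_bytes)
    stop(sprintf(
      "rf_container_size_error: frames.bin holds %d bytes, expected %d (%d frames x %d lines x %d samples x 4)",
      actual_bytes, expected_bytes, nf, nl, ns))
  con <- file(bin_path, "rb")
  on.exit(close(con))
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    v <- readBin(con, "numeric", n = nl * ns, size = 4L, endian = "little")
    frames[[f]] <- matrix(v, nrow = nl, byrow = TRUE)
  }
  list(frames = frames, meta = meta)
}

#' Read a two-section case from a pair of RF containers
#'
#' Expects subdirectories `transverse/` and `longitudinal/` under `path`,
#' each a container written by [write_rf_container()], and returns a
#' `case_recording` compatible with [extract_case_features()].
#'
#' @param path Case directory.
#' @param roi Optional [roi_spec()] to attach as the case ROI (default:
#'   full frame).
#' @return A `case_recording`.
#' @export
read_rf_case <- function(path, roi = NULL) {
  secs <- lapply(c(transverse = "transverse", longitudinal = "longitudinal"),
                 function(s) read_rf_container(file.path(path, s)))
  meta <- secs$transverse$meta
  acq <- acquisition_config(
    sampling_rate_hz = meta$sampling_rate_hz,
    lines_per_frame = meta$lines_per_frame,
    samples_per_line = meta$samples_per_line,
    n_frames = meta$n_frames,
    tx_frequency_hz = meta$tx_frequency_hz,
    rx_center_frequency_hz = meta$rx_center_frequency_hz)
  if (is.null(roi))
    roi <- roi_spec(0, meta$lines_per_frame, 0, meta$samples_per_line)
  structure(list(sections = lapply(secs, `[[`, "frames"), roi = roi,
                 acq = acq, seed = NA_integer_),
            class = "case_recording")
}

#' Cohort and ROI table I/O
#'
#' The cohort table is a plain CSV with one row per nodule (columns:
#' `nodule_id`, `clnm`, the continuous measurements, the 0-based ordinal
#' category codes, and the RF feature columns). Empty cells are missing
#' values; analyses drop incomplete rows per-variable with a logged count.
#' The ROI table is a CSV with columns `case_id`, `section`, `frame_index`,
#' `reader`, `line_start`, `line_stop`, `sample_start`, `sample_stop`
#' (0-based, half-open).
#'
#' @param cohort A cohort data.frame (as from [simulate_cohort()]).
#' @param path CSV file path.
#' @return Readers return data.frames; writers return the path invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (!"clnm" %in% names(df)) stop("cohort_schema_error: missing 'clnm' column")
  df
}

#' @rdname write_cohort_csv
#' @export
read_roi_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("case_id", "section", "frame_index", "reader",
                "line_start", "line_stop", "sample_start", "sample_stop")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("roi_schema_error: missing column(s): ", paste(missing, collapse = ", "))
  df
}
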