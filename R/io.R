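#' Read a multi-channel MEA recording
#'
#' Two on-disk dialects are supported.
#'
#' **HDF5 (native layout):** root attributes `sample_rate_hz` and
#' `n_channels`; dataset `/recording/channel_data` shaped
#' channels x samples (float64); optional `/recording/time_s`; optional
#' group `/ground_truth` with `peak_times_s` written by the simulator. If
#' the native dataset is absent, a vendor-style nested path
#' `/Data/Recording_0/AnalogStream/Stream_0/ChannelData` is attempted as a
#' best-effort fallback (sample rate then taken from `sample_rate` argument
#' or defaulting to 10 kHz with a warning).
#'
#' **CSV:** header row required; first column is time in seconds, remaining
#' columns are channels (`time,ch0,ch1,...`). The sample rate is inferred
#' from the time column.
#'
#' @param path File path.
#' @param format `"hdf5"` or `"csv"`; default guesses from the extension.
#' @param sample_rate Optional override used only by the vendor-style HDF5
#'   fallback, which stores no rate in our reachable layout.
#' @return A [recording_set()]. Channel order is preserved.
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "hdf5", "csv"),
                           sample_rate = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5" else "csv"
  }
  if (!file.exists(path)) stop("input file does not exist: ", path)
  switch(format,
    hdf5 = read_recording_h5(path, sample_rate),
    csv = read_recording_csv(path)
  )
}

read_recording_h5 <- function(path, sample_rate = NULL) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  full <- file.path(contents$group, contents$name)
  full <- sub("^//", "/", full)
  src <- sub("\\.(h5|hdf5)$", "", basename(path), ignore.case = TRUE)
  if ("/recording/channel_data" %in% full) {
    att <- rhdf5::h5readAttributes(path, "/")
    if (is.null(att$sample_rate_hz))
      stop("HDF5 format error: missing root attribute 'sample_rate_hz'")
    m <- rhdf5::h5read(path, "recording/channel_data")
    rec <- recording_set(m, sample_rate = as.numeric(att$sample_rate_hz),
                         source_id = src)
    if ("/ground_truth/peak_times_s" %in% full) {
      rec$metadata$ground_truth_peak_times_s <-
        as.numeric(rhdf5::h5read(path, "ground_truth/peak_times_s"))
    }
    return(rec)
  }
  vendor <- "/Data/Recording_0/AnalogStream/Stream_0/ChannelData"
  if (vendor %in% full) {
    m <- rhdf5::h5read(path, vendor)
    if (is.null(sample_rate)) {
      warning("vendor-style HDF5: no sample rate found, assuming 10 kHz")
      sample_rate <- 10000
    }
    return(recording_set(m, sample_rate = sample_rate, source_id = src))
  }
  stop(
    "HDF5 format error: expected dataset '/recording/channel_data' ",
    "(native layout) or '", vendor, "' (vendor-style fallback) in ", path
  )
}

read_recording_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L)
    stop("CSV format error: need a time column plus at least one channel")
  if (nrow(df) < 2L) stop("CSV format error: need at least 2 rows")
  tm <- as.numeric(df[[1L]])
  dt <- diff(tm)
  if (any(dt <= 0)) stop("CSV integrity error: time column must increase")
  if (max(abs(dt - dt[1L])) > 1e-6 * dt[1L])
    stop("CSV integrity error: time column must be uniformly spaced")
  sr <- 1 / dt[1L]
  src <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
  traces <- lapply(seq_len(ncol(df) - 1L), function(i) {
    recording_trace(as.numeric(df[[i + 1L]]), sample_rate = sr,
                    channel_id = i - 1L, t0 = tm[1L], source_id = src)
  })
  recording_set(traces)
}

#' Write a multi-channel MEA recording
#'
#' Writes the native HDF5 dialect (see [read_recording()]) or the CSV
#' dialect. HDF5 round-trips samples bit-exactly; CSV round-trips to the
#' printed precision (15 significant digits).
#'
#' @param rec A [recording_set()].
#' @param path Output file path.
#' @param format `"hdf5"` or `"csv"`; default guesses from the extension.
#' @param ground_truth Optional list with numeric `cp_times_s` (and
#'   optionally `rp_times_s`, `burst_membership`) stored under
#'   `/ground_truth` in the HDF5 layout; ignored for CSV.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "hdf5", "csv"),
                            ground_truth = NULL) {
  stopifnot(inherits(rec, "recording_set"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5" else "csv"
  }
  if (format == "hdf5") {
    write_recording_h5(rec, path, ground_truth)
  } else {
    write_recording_csv(rec, path)
  }
  invisible(path)
}

write_recording_h5 <- function(rec, path, ground_truth = NULL) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (file.exists(path)) file.remove(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) stop("cannot create HDF5 file: ", path)
  rhdf5::h5createGroup(path, "recording")
  rhdf5::h5write(set_matrix(rec), path, "recording/channel_data")
  rhdf5::h5write(trace_times(rec$traces[[1L]]), path, "recording/time_s")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(rec$sample_rate, fid, "sample_rate_hz")
  rhdf5::h5writeAttribute(as.integer(rec$n_channels), fid, "n_channels")
  rhdf5::H5Fclose(fid)
  if (!is.null(ground_truth)) {
    rhdf5::h5createGroup(path, "ground_truth")
    rhdf5::h5write(as.numeric(ground_truth$cp_times_s), path,
                   "ground_truth/peak_times_s")
    if (!is.null(ground_truth$burst_membership))
      rhdf5::h5write(as.integer(ground_truth$burst_membership), path,
                     "ground_truth/burst_membership")
    if (length(ground_truth$rp_times_s))
      rhdf5::h5write(as.numeric(ground_truth$rp_times_s), path,
                     "ground_truth/rp_times_s")
  }
  invisible(path)
}

write_recording_csv <- function(rec, path) {
  m <- t(set_matrix(rec))
  df <- data.frame(time = trace_times(rec$traces[[1L]]), m)
  names(df) <- c("time", paste0("ch", seq_len(rec$n_channels) - 1L))
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a classified event table as CSV
#'
#' Columns: `source_id, event_index, t_start_s, t_end_s, duration_s, class,
#' burst_index` (empty `burst_index` for intervals outside bursts).
#'
#' @param events A `cp_events` table from [classify_intervals()], or a list
#'   of them (concatenated).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  if (inherits(events, "cp_events")) events <- list(events)
  df <- do.call(rbind, lapply(events, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a detected peak train as CSV with a JSON parameter sidecar
#'
#' The CSV has columns `source_id, peak_index, time_s`; a `<path>.json`
#' sidecar archives the [detection_params()] used, for provenance.
#'
#' @param train A `cp_train` from [detect_peaks()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peaks_csv <- function(train, path) {
  stopifnot(inherits(train, "cp_train"))
  df <- data.frame(
    source_id = train$source_id,
    peak_index = seq_along(train$peak_times),
    time_s = train$peak_times
  )
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(unclass(train$params), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
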