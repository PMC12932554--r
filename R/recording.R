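#' One channel of a multielectrode-array recording
#'
#' A uniformly sampled voltage series from a single electrode. Sample `k`
#' (1-based in R) is taken at time `t0 + (k - 1) / sample_rate`; channel
#' indices are 0-based throughout the package, matching common MEA export
#' conventions.
#'
#' @param samples Numeric vector of voltages (device-native units),
#'   length >= 2.
#' @param sample_rate Sampling rate in Hz, > 0.
#' @param channel_id 0-based integer channel index.
#' @param t0 Start time in seconds (default 0).
#' @param source_id Recording/file identifier string.
#'
#' @return An object of class `recording_trace`.
#' @examples
#' tr <- recording_trace(sin(seq(0, 1, by = 1e-3)), sample_rate = 1000)
#' tr
#' @export
recording_trace <- function(samples, sample_rate, channel_id = 0L,
                            t0 = 0, source_id = "recording") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("'samples' must have length >= 2")
  if (anyNA(samples)) stop("'samples' must not contain NA")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("'sample_rate' must be a single positive number")
  structure(
    list(
      channel_id = as.integer(channel_id),
      sample_rate = as.numeric(sample_rate),
      samples = samples,
      t0 = as.numeric(t0),
      source_id = as.character(source_id)
    ),
    class = "recording_trace"
  )
}

#' Sample times of a recording trace
#' @param trace A [recording_trace()].
#' @return Numeric vector of times in seconds, one per sample.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "recording_trace"))
  trace$t0 + (seq_along(trace$samples) - 1) / trace$sample_rate
}

#' Duration of a recording trace
#'
#' Time of the last sample relative to `t0 = 0` origin, i.e. the recording
#' length used as `final_time` by the event analysis.
#' @param trace A [recording_trace()].
#' @return Length in seconds.
#' @export
trace_duration <- function(trace) {
  stopifnot(inherits(trace, "recording_trace"))
  trace$t0 + (length(trace$samples) - 1) / trace$sample_rate
}

#' @export
print.recording_trace <- function(x, ...) {
  cat(sprintf(
    "recording_trace: channel %d of '%s', %d samples at %g Hz (%.3f s)\n",
    x$channel_id, x$source_id, length(x$samples), x$sample_rate,
    (length(x$samples) - 1) / x$sample_rate
  ))
  invisible(x)
}

#' A multi-channel MEA recording
#'
#' Collection of [recording_trace()] objects sharing one time base: all
#' channels must have identical sampling rate and length (the MEA device
#' records all electrodes synchronously).
#'
#' @param traces List of [recording_trace()] objects, one per channel, or a
#'   numeric matrix with one row per channel.
#' @param sample_rate Sampling rate in Hz; required when `traces` is a
#'   matrix, ignored otherwise.
#' @param source_id Recording identifier, used when `traces` is a matrix.
#' @param metadata Free-form named list.
#'
#' @return An object of class `recording_set` with elements `traces`,
#'   `n_channels`, `sample_rate`, `metadata`.
#' @examples
#' m <- matrix(rnorm(300), nrow = 3)
#' rec <- recording_set(m, sample_rate = 100)
#' rec$n_channels
#' @export
recording_set <- function(traces, sample_rate = NULL,
                          source_id = "recording", metadata = list()) {
  if (is.matrix(traces)) {
    if (is.null(sample_rate))
      stop("'sample_rate' is required when 'traces' is a matrix")
    traces <- lapply(seq_len(nrow(traces)), function(i) {
      recording_trace(traces[i, ], sample_rate,
                      channel_id = i - 1L, source_id = source_id)
    })
  }
  if (!is.list(traces) || length(traces) == 0L)
    stop("'traces' must be a non-empty list of recording_trace objects")
  ok <- vapply(traces, inherits, logical(1), "recording_trace")
  if (!all(ok)) stop("all elements of 'traces' must be recording_trace objects")
  sr <- vapply(traces, `[[`, numeric(1), "sample_rate")
  n <- vapply(traces, function(t) length(t$samples), integer(1))
  if (length(unique(sr)) != 1L)
    stop("all traces must share one sample_rate")
  if (length(unique(n)) != 1L)
    stop("ragged recording: all traces must have the same length")
  structure(
    list(
      traces = traces,
      n_channels = length(traces),
      sample_rate = sr[[1L]],
      metadata = metadata
    ),
    class = "recording_set"
  )
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf(
    "recording_set: %d channels x %d samples at %g Hz (%.3f s) [%s]\n",
    x$n_channels, length(x$traces[[1L]]$samples), x$sample_rate,
    (length(x$traces[[1L]]$samples) - 1) / x$sample_rate,
    x$traces[[1L]]$source_id
  ))
  invisible(x)
}

# channel matrix view (rows = channels), used by I/O and channel selection
set_matrix <- function(rec) {
  stopifnot(inherits(rec, "recording_set"))
  do.call(rbind, lapply(rec$traces, `[[`, "samples"))
}
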