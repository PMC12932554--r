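#' Normalise a voltage trace to unit peak amplitude
#'
#' Divides every sample by the maximum *absolute* value of the trace, so
#' the output has max |value| = 1 while keeping waveform polarity.
#' Extracellular deflections can be negative-going; dividing by the signed
#' maximum would flip the polarity of a negative-dominant trace, so the
#' absolute maximum is used as the scale.
#'
#' @param x Numeric vector, or a [recording_trace()].
#' @return Numeric vector of the same length with max |value| = 1.
#' @examples
#' normalize_signal(c(2, 4, 1))   # 0.5 1.0 0.25
#' normalize_signal(c(-4, 2))     # -1.0 0.5
#' @export
normalize_signal <- function(x) {
  if (inherits(x, "recording_trace")) x <- x$samples
  x <- as.numeric(x)
  if (length(x) == 0L) stop("empty signal")
  m <- max(abs(x))
  if (m == 0) stop("degenerate input: signal is identically zero")
  x / m
}

# centered moving average, truncated (not padded) at the edges.
# O(n) via cumulative sums; window of N samples covers indices
# j - floor(N/2) .. j + (N - 1 - floor(N/2)) where available.
moving_average <- function(x, n) {
  n <- as.integer(n)
  len <- length(x)
  if (n < 1L) stop("'average_window' must be >= 1")
  if (n > len) stop("'average_window' (", n, ") exceeds signal length (", len, ")")
  if (n == 1L) return(as.numeric(x))
  lo_off <- n %/% 2L
  hi_off <- n - 1L - lo_off
  cs <- cumsum(c(0, x))
  idx <- seq_len(len)
  lo <- pmax(idx - lo_off, 1L)
  hi <- pmin(idx + hi_off, len)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Moving-average smoothing
#'
#' Centred moving average with a window of `average_window` samples; at the
#' edges the window is truncated to the available samples (no padding, so
#' no phantom values enter the mean). Output length equals input length.
#' The filter is linear and preserves the mean of stationary interiors.
#'
#' @param x Numeric vector (typically a normalised signal).
#' @param average_window Window length in samples, >= 1 and <= `length(x)`.
#' @return Numeric vector of smoothed values.
#' @examples
#' smooth_signal(c(0, 1, 0), 3)  # 0.5 1/3 0.5
#' @export
smooth_signal <- function(x, average_window = 200L) {
  moving_average(as.numeric(x), average_window)
}

#' Normalise and smooth one channel for peak detection
#'
#' Applies [normalize_signal()] then [smooth_signal()] to a single-channel
#' trace, producing the object the detector consumes.
#'
#' @param trace A [recording_trace()].
#' @param average_window Moving-average window in samples (default 200,
#'   i.e. 20 ms at 10 kHz).
#' @return An object of class `smoothed_trace` with fields `times`,
#'   `signal_norm`, `signal_mean`, `average_window`, `sample_rate`,
#'   `source_id`, `channel_id`, `final_time`.
#' @examples
#' tr <- recording_trace(sin(seq(0, 2, 1e-3)), 1000)
#' st <- preprocess_trace(tr, average_window = 20)
#' max(abs(st$signal_norm))  # 1
#' @export
preprocess_trace <- function(trace, average_window = 200L) {
  stopifnot(inherits(trace, "recording_trace"))
  sn <- normalize_signal(trace$samples)
  sm <- smooth_signal(sn, average_window)
  structure(
    list(
      times = trace_times(trace),
      signal_norm = sn,
      signal_mean = sm,
      average_window = as.integer(average_window),
      sample_rate = trace$sample_rate,
      source_id = trace$source_id,
      channel_id = trace$channel_id,
      final_time = trace_duration(trace)
    ),
    class = "smoothed_trace"
  )
}

#' @export
print.smoothed_trace <- function(x, ...) {
  cat(sprintf(
    "smoothed_trace: '%s' channel %d, %d samples at %g Hz, window %d samples\n",
    x$source_id, x$channel_id, length(x$signal_mean), x$sample_rate,
    x$average_window
  ))
  invisible(x)
}
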