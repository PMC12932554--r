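#' Detect contraction-pulse peaks in a smoothed trace
#'
#' Scans the smoothed signal left to right and accepts sample \eqn{i} as a
#' peak iff three conditions hold jointly:
#' \enumerate{
#'   \item the smoothed signal exceeds the normalised threshold,
#'   \item the first derivative is positive (a rising edge),
#'   \item the second derivative changes sign from positive to negative
#'     within the \eqn{\pm\theta/2} stencil around \eqn{t_i} (the onset of
#'     concave-down curvature that marks a pulse apex).
#' }
#' Derivatives are the centred finite differences of
#' [first_derivative()] / [second_derivative()]. After each accepted peak
#' the scan pointer jumps past `refractory_period`, so samples inside the
#' refractory window are never evaluated and overlapping detections of one
#' pulse are impossible. The reported peak time is the accepted sample's
#' own timestamp (no sub-sample interpolation).
#'
#' @param smoothed A `smoothed_trace` from [preprocess_trace()]; its
#'   `average_window` should match `params$average_window`.
#' @param params A [detection_params()] object (or a list coercible to
#'   one).
#' @return An object of class `cp_train`: fields `source_id`,
#'   `peak_times` (strictly increasing absolute seconds, spacing >=
#'   `refractory_period`), `final_time`, `params`, `channel_id`.
#' @examples
#' t <- seq(0, 10, by = 1e-3)
#' x <- exp(-(t - 5)^2 / (2 * 0.05^2))          # one pulse at 5 s
#' tr <- recording_trace(x, sample_rate = 1000)
#' st <- preprocess_trace(tr, average_window = 20)
#' p <- detection_params(average_window = 20, time_threshold = 0.02)
#' detect_peaks(st, p)$peak_times               # one time near 5 s
#' @export
detect_peaks <- function(smoothed, params = detection_params()) {
  stopifnot(inherits(smoothed, "smoothed_trace"))
  params <- as_detection_params(params)
  if (smoothed$average_window != params$average_window)
    warning("smoothed trace was built with average_window ",
            smoothed$average_window, " but params specify ",
            params$average_window)
  x <- smoothed$signal_mean
  tm <- smoothed$times
  dt <- 1 / smoothed$sample_rate
  m <- theta_half_steps(dt, params$time_threshold)
  f1 <- first_derivative(x, dt, params$time_threshold)
  f2 <- second_derivative(f1, dt, params$time_threshold)
  n <- length(x)

  # sign transitions of f'' from positive to non-positive between k, k+1
  cross <- logical(n)
  k <- seq_len(n - 1L)
  cross[k] <- !is.na(f2[k]) & !is.na(f2[k + 1L]) &
    f2[k] > 0 & f2[k + 1L] <= 0
  ccross <- cumsum(cross)
  # condition (c): any crossing within [i - m, i + m - 1]
  lo <- pmax(seq_len(n) - m, 1L)
  hi <- pmin(seq_len(n) + m - 1L, n)
  has_cross <- (ccross[hi] - c(0L, ccross)[lo]) > 0L

  cand <- which(
    x > params$normalized_threshold &
      !is.na(f1) & f1 > 0 &
      has_cross
  )
  if (all(is.na(f1)))
    stop("record too short: derivative stencil unavailable everywhere")

  peaks <- numeric(0)
  j <- 1L
  while (j <= length(cand)) {
    t_acc <- tm[cand[j]]
    peaks <- c(peaks, t_acc)
    # skip ahead past the refractory period
    while (j <= length(cand) && tm[cand[j]] <= t_acc + params$refractory_period)
      j <- j + 1L
  }

  structure(
    list(
      source_id = smoothed$source_id,
      channel_id = smoothed$channel_id,
      peak_times = peaks,
      final_time = smoothed$final_time,
      params = params
    ),
    class = "cp_train"
  )
}

#' @export
print.cp_train <- function(x, ...) {
  cat(sprintf(
    "cp_train: %d peaks in '%s' (channel %d), record length %.3f s\n",
    length(x$peak_times), x$source_id, x$channel_id, x$final_time
  ))
  if (length(x$peak_times)) {
    show <- utils::head(x$peak_times, 8L)
    cat("  first peaks (s):", paste(sprintf("%.3f", show), collapse = ", "),
        if (length(x$peak_times) > 8L) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
plot.cp_train <- function(x, ...) {
  graphics::plot(
    x$peak_times, rep(1, length(x$peak_times)), type = "h",
    ylim = c(0, 1), yaxt = "n", xlab = "time (s)", ylab = "",
    main = sprintf("Detected peaks: %s", x$source_id), ...
  )
  invisible(x)
}

#' Detect peaks in a multi-channel recording
#'
#' Convenience wrapper: selects the analysis channel (highest SNR by
#' default, see [select_best_channel()]), preprocesses it, and runs
#' [detect_peaks()].
#'
#' @param rec A [recording_set()].
#' @param params A [detection_params()].
#' @param channel Optional explicit 0-based channel index; default `NULL`
#'   selects by SNR.
#' @return A `cp_train`.
#' @export
analyze_recording <- function(rec, params = detection_params(), channel = NULL) {
  stopifnot(inherits(rec, "recording_set"))
  params <- as_detection_params(params)
  if (is.null(channel)) channel <- select_best_channel(rec)
  trace <- rec$traces[[channel + 1L]]
  st <- preprocess_trace(trace, params$average_window)
  detect_peaks(st, params)
}
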