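#' Select the analysis channel by signal-to-noise ratio
#'
#' MEA recordings of a whole animal show the same events on every channel
#' with very different amplitudes (electrode-tissue coupling varies), so a
#' single best-coupled channel is analysed rather than a channel average,
#' which would dilute low-amplitude physiological events below the
#' detection threshold.
#'
#' The default SNR statistic needs no prior peak detection: the
#' peak-to-peak amplitude of the moving-average smoothed trace divided by a
#' robust noise scale, the median absolute deviation of the first
#' difference rescaled to standard-deviation units (for white noise of
#' standard deviation \eqn{\sigma} the first difference has standard
#' deviation \eqn{\sigma\sqrt{2}}, so the estimate is
#' \eqn{\mathrm{mad}(\Delta x)/\sqrt{2}}). The statistic is invariant to a
#' common rescaling of all channels and monotone in per-channel gain.
#'
#' @param rec A [recording_set()].
#' @param snr_window Smoothing window (samples) used before the
#'   peak-to-peak measurement; default 200.
#' @param scorer Optional function `(samples, sample_rate) -> numeric`
#'   replacing the default SNR statistic.
#' @return 0-based index of the channel with the highest score; ties are
#'   broken by the lowest index.
#' @examples
#' m <- rbind(0.2 * sin(1:500 / 10), sin(1:500 / 10))
#' rec <- recording_set(m + 0.01 * matrix(rnorm(1000), 2), sample_rate = 100)
#' select_best_channel(rec)  # 1, the high-gain channel
#' @export
select_best_channel <- function(rec, snr_window = 200L, scorer = NULL) {
  stopifnot(inherits(rec, "recording_set"))
  if (is.null(scorer)) {
    scorer <- function(x, sr) {
      w <- min(as.integer(snr_window), length(x))
      sm <- moving_average(x, w)
      noise <- stats::mad(diff(x)) / sqrt(2)
      ptp <- max(sm) - min(sm)
      if (noise == 0) {
        if (ptp == 0) return(NA_real_)  # flat channel, no information
        return(Inf)                      # noiseless signal
      }
      ptp / noise
    }
  }
  scores <- vapply(rec$traces, function(tr) scorer(tr$samples, tr$sample_rate),
                   numeric(1))
  if (all(is.na(scores)))
    stop("degenerate input: every channel is constant, SNR undefined")
  which.max(scores) - 1L  # which.max ignores NA, keeps first of ties
}
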