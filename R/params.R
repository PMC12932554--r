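#' Detection parameters for contraction-pulse sorting
#'
#' Bundles every tunable threshold of the detector and interval classifier.
#' The defaults are working values for Hydra MEA recordings sampled at
#' 10 kHz; all of them are expected to be tuned per preparation and can be
#' overridden here or in a CLI configuration file.
#'
#' @param normalized_threshold Amplitude gate on the smoothed, normalised
#'   signal, dimensionless in (0, 1). A candidate sample must exceed it.
#' @param average_window Moving-average window length in samples (the
#'   "average threshold"). Default 200 samples, i.e. 20 ms at 10 kHz.
#' @param time_threshold Derivative step \eqn{\theta} in seconds: the
#'   centred finite difference uses samples \eqn{\theta/2} either side of
#'   the evaluation point. Must map to an even number (>= 2) of sample
#'   intervals. Default 0.02 s.
#' @param refractory_period Dead time in seconds after an accepted peak
#'   during which no further peak may be accepted. Default 1 s.
#' @param cp_threshold Inter-peak intervals strictly below this duration
#'   (seconds) are classified as contraction-pulse (CP) intervals, i.e.
#'   burst components. Default 10 s.
#' @param icbi_threshold Intervals at or above this duration (seconds) are
#'   inter-contraction burst intervals (IcBI). Must be >= `cp_threshold`;
#'   with the two equal (the default) the classification is a binary split.
#' @param count_convention How contraction pulses are counted per burst:
#'   `"intervals"` counts CP-classified intervals in the run (so nCP equals
#'   the number of CP intervals and matches CTime = sum of CPIs),
#'   `"peaks"` counts the peaks bounding the run (one more per burst).
#'
#' @return An object of class `detection_params` (a validated list).
#' @examples
#' detection_params()
#' detection_params(normalized_threshold = 0.5, refractory_period = 0.3)
#' @export
detection_params <- function(normalized_threshold = 0.3,
                             average_window = 200L,
                             time_threshold = 0.02,
                             refractory_period = 1.0,
                             cp_threshold = 10,
                             icbi_threshold = cp_threshold,
                             count_convention = c("intervals", "peaks")) {
  count_convention <- match.arg(count_convention)
  stopifnot(
    is.numeric(normalized_threshold), length(normalized_threshold) == 1L,
    is.numeric(average_window), length(average_window) == 1L,
    is.numeric(time_threshold), length(time_threshold) == 1L,
    is.numeric(refractory_period), length(refractory_period) == 1L,
    is.numeric(cp_threshold), length(cp_threshold) == 1L,
    is.numeric(icbi_threshold), length(icbi_threshold) == 1L
  )
  if (normalized_threshold <= 0 || normalized_threshold >= 1)
    stop("'normalized_threshold' must lie strictly in (0, 1)")
  if (average_window < 1) stop("'average_window' must be >= 1 sample")
  if (time_threshold <= 0) stop("'time_threshold' must be positive")
  if (refractory_period < 0) stop("'refractory_period' must be >= 0")
  if (cp_threshold <= 0) stop("'cp_threshold' must be positive")
  if (icbi_threshold < cp_threshold)
    stop("'icbi_threshold' must be >= 'cp_threshold'")
  structure(
    list(
      normalized_threshold = as.numeric(normalized_threshold),
      average_window = as.integer(average_window),
      time_threshold = as.numeric(time_threshold),
      refractory_period = as.numeric(refractory_period),
      cp_threshold = as.numeric(cp_threshold),
      icbi_threshold = as.numeric(icbi_threshold),
      count_convention = count_convention
    ),
    class = "detection_params"
  )
}

#' @export
print.detection_params <- function(x, ...) {
  cat("Contraction-pulse detection parameters\n")
  cat(sprintf("  normalized threshold : %.3g\n", x$normalized_threshold))
  cat(sprintf("  average window       : %d samples\n", x$average_window))
  cat(sprintf("  time threshold (theta): %.4g s\n", x$time_threshold))
  cat(sprintf("  refractory period    : %.4g s\n", x$refractory_period))
  cat(sprintf("  CP threshold         : %.4g s\n", x$cp_threshold))
  cat(sprintf("  IcBI threshold       : %.4g s\n", x$icbi_threshold))
  cat(sprintf("  count convention     : %s\n", x$count_convention))
  invisible(x)
}

as_detection_params <- function(x) {
  if (inherits(x, "detection_params")) return(x)
  if (is.list(x)) return(do.call(detection_params, x))
  stop("cannot interpret 'params' as detection parameters")
}
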