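# Independent brute-force oracles and small fixture builders.
# These deliberately use naive loops, not the package's vectorised code.

# one-line-per-interval classifier with explicit burst bookkeeping
classify_oracle <- function(peaks, t_last, cp_thr, icbi_thr = cp_thr) {
  durs <- c(diff(peaks), t_last - peaks[length(peaks)])
  cls <- character(length(durs))
  for (i in seq_along(durs)) {
    cls[i] <- if (durs[i] < cp_thr) "CP"
    else if (durs[i] >= icbi_thr) "IcBI"
    else "ambiguous"
  }
  bi <- rep(NA_integer_, length(durs))
  b <- 0L
  in_burst <- FALSE
  for (i in seq_along(cls)) {
    if (cls[i] == "CP") {
      if (!in_burst) {
        b <- b + 1L
        in_burst <- TRUE
      }
      bi[i] <- b
    } else {
      in_burst <- FALSE
    }
  }
  list(durations = durs, class = cls, burst_index = bi)
}

# brute-force peak finder: local maxima of the smoothed signal above a
# threshold, then greedy left-to-right thinning by a dead time
local_max_oracle <- function(x, times, threshold, dead_time) {
  n <- length(x)
  is_max <- logical(n)
  for (i in 2:(n - 1)) {
    is_max[i] <- x[i] > threshold && x[i] >= x[i - 1] && x[i] > x[i + 1]
  }
  cand <- times[is_max]
  keep <- numeric(0)
  for (tt in cand) {
    if (!length(keep) || tt - keep[length(keep)] > dead_time) {
      keep <- c(keep, tt)
    }
  }
  keep
}

# greedy one-to-one matching of detected vs planted times within tol
match_events <- function(detected, planted, tol) {
  used <- logical(length(detected))
  matched <- 0L
  for (tp in planted) {
    d <- abs(detected - tp)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  list(
    matched = matched,
    precision = if (length(detected)) matched / length(detected) else NA_real_,
    recall = if (length(planted)) matched / length(planted) else NA_real_
  )
}

# a minimal cp_train object without running the detector
make_train <- function(peaks, final_time, source_id = "t",
                       params = detection_params()) {
  structure(
    list(source_id = source_id, channel_id = 0L, peak_times = peaks,
         final_time = final_time, params = params),
    class = "cp_train"
  )
}

# single-channel trace containing Gaussian pulses at given apex times
pulse_trace <- function(apex_times, height = 0.9, width = 0.008,
                        duration = 10, sr = 1000, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = 1 / sr)
  x <- numeric(length(t))
  for (a in apex_times) x <- x + height * exp(-(t - a)^2 / (2 * width^2))
  if (noise > 0) x <- x + rnorm(length(t), 0, noise)
  recording_trace(x, sample_rate = sr, source_id = "pulse_fixture")
}

# random aligned peak train: first peak at 0, exponential-ish gaps
random_train <- function(n_peaks, gap_scale = 5) {
  gaps <- rexp(n_peaks - 1, rate = 1 / gap_scale) + 1e-3
  peaks <- c(0, cumsum(gaps))
  t_last <- peaks[length(peaks)] + rexp(1, 1 / gap_scale) + 1e-3
  list(peaks = peaks, t_last = t_last)
}
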