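#' Configuration for the synthetic MEA recording simulator
#'
#' Describes a burst-structured contraction-pulse pattern of the kind seen
#' in Hydra MEA recordings: bursts of high-amplitude biphasic pulses
#' recurring on a minutes time scale, channel-synchronous event timing
#' with per-channel amplitude variation, optional low-amplitude rhythmic
#' potentials between bursts, and additive white noise. Defaults emulate a
#' spontaneously active animal on a 60-electrode array sampled at 10 kHz:
#' about one contraction burst per minute, five pulses per burst a few
#' seconds apart, 10 ms pulse templates, and per-channel log-normal gain
#' spread (coupling varies strongly across electrodes).
#'
#' @param duration_s Recording length in seconds (default 600, the order
#'   of the 10-minute sessions typical for this preparation).
#' @param sample_rate_hz Sampling rate (default 10000).
#' @param n_channels Number of electrodes (default 60).
#' @param burst_rate Bursts per minute governing the renewal process of
#'   burst onsets (default 1).
#' @param burst_interval_cv Coefficient of variation of the
#'   gamma-distributed inter-onset intervals (default 0.3).
#' @param intra_burst_interval_s Mean intra-burst inter-pulse interval in
#'   seconds (default 3).
#' @param intra_burst_cv Coefficient of variation of the gamma-distributed
#'   intra-burst intervals (default 0.3).
#' @param peaks_per_burst Mean pulses per burst; each burst plants
#'   `1 + Poisson(peaks_per_burst - 1)` pulses (default 5).
#' @param cp_amplitude Contraction-pulse amplitude in normalised units
#'   (default 1).
#' @param cp_width_s Width (Gaussian sigma) of the pulse template in
#'   seconds (default 0.01). The template is a difference of two Gaussians
#'   (widths `cp_width_s` and `2 cp_width_s`), giving the biphasic
#'   centre-surround shape of an extracellular field potential.
#' @param rp_amplitude Rhythmic-potential amplitude, 0 disables them
#'   (default 0). Must be below `cp_amplitude`.
#' @param rp_rate_hz Poisson rate of rhythmic potentials (default 0.1).
#' @param noise_sigma Standard deviation of the additive white noise per
#'   channel, in normalised units (default 0.05).
#' @param channel_gains Numeric vector of per-channel multipliers, or
#'   `NULL` to draw them log-normally (sdlog 0.5) per channel.
#' @param slowdown_factor Multiplier >= 1 applied to every sampled
#'   inter-event interval; models the rate slowdown seen under
#'   anaesthesia (default 1).
#' @param seed Integer seed; identical seed and configuration give
#'   bit-identical output.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 600,
                         sample_rate_hz = 10000,
                         n_channels = 60L,
                         burst_rate = 1,
                         burst_interval_cv = 0.3,
                         intra_burst_interval_s = 3,
                         intra_burst_cv = 0.3,
                         peaks_per_burst = 5,
                         cp_amplitude = 1,
                         cp_width_s = 0.01,
                         rp_amplitude = 0,
                         rp_rate_hz = 0.1,
                         noise_sigma = 0.05,
                         channel_gains = NULL,
                         slowdown_factor = 1,
                         seed = 1L) {
  stopifnot(
    duration_s > 0, sample_rate_hz > 0, n_channels >= 1,
    burst_rate >= 0, burst_interval_cv > 0,
    intra_burst_interval_s > 0, intra_burst_cv > 0,
    peaks_per_burst >= 1, cp_width_s > 0,
    rp_rate_hz >= 0, noise_sigma >= 0, slowdown_factor >= 1
  )
  if (!(cp_amplitude > rp_amplitude) || rp_amplitude < 0)
    stop("need cp_amplitude > rp_amplitude >= 0")
  if (!is.null(channel_gains)) {
    if (length(channel_gains) != n_channels)
      stop("'channel_gains' must have one entry per channel")
    if (any(channel_gains <= 0)) stop("'channel_gains' must be positive")
  }
  structure(
    list(
      duration_s = duration_s, sample_rate_hz = sample_rate_hz,
      n_channels = as.integer(n_channels),
      burst_rate = burst_rate, burst_interval_cv = burst_interval_cv,
      intra_burst_interval_s = intra_burst_interval_s,
      intra_burst_cv = intra_burst_cv,
      peaks_per_burst = peaks_per_burst,
      cp_amplitude = cp_amplitude, cp_width_s = cp_width_s,
      rp_amplitude = rp_amplitude, rp_rate_hz = rp_rate_hz,
      noise_sigma = noise_sigma, channel_gains = channel_gains,
      slowdown_factor = slowdown_factor, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    paste0("synth_config: %.0f s x %d ch at %g Hz; %.2g bursts/min ",
           "(slowdown %.2g), %.2g peaks/burst every %.2g s; noise %.3g\n"),
    x$duration_s, x$n_channels, x$sample_rate_hz, x$burst_rate,
    x$slowdown_factor, x$peaks_per_burst, x$intra_burst_interval_s,
    x$noise_sigma
  ))
  invisible(x)
}

# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# gamma draw parameterised by mean and coefficient of variation
rgamma_mean_cv <- function(n, mean, cv) {
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

# biphasic pulse template: difference of two Gaussians, unit apex at 0
pulse_template <- function(t, width) {
  a <- 0.4
  raw <- exp(-t^2 / (2 * width^2)) - a * exp(-t^2 / (2 * (2 * width)^2))
  raw / (1 - a)
}

#' Simulate a multi-channel MEA recording with ground truth
#'
#' Burst onsets are drawn from a gamma renewal process at `burst_rate`;
#' each burst plants `1 + Poisson(peaks_per_burst - 1)` contraction pulses
#' separated by gamma-distributed intra-burst intervals. Every pulse is
#' rendered as a biphasic difference-of-Gaussians template scaled by
#' `cp_amplitude`; an optional Poisson train of lower-amplitude rhythmic
#' potentials is rendered the same way. All channels share the event
#' times and differ only by `channel_gains`; independent white Gaussian
#' noise of `noise_sigma` is added per channel. `slowdown_factor`
#' multiplies every sampled interval (the anaesthesia scenario).
#'
#' @param config A [synth_config()].
#' @param params A [detection_params()] used to compute the ground-truth
#'   activity metrics implied by the planted times.
#' @return A list of class `synth_recording`:
#'   \describe{
#'     \item{recording}{a [recording_set()]}
#'     \item{truth}{list with `cp_times_s`, `burst_membership`,
#'       `rp_times_s`, `channel_gains`, and `true_metrics` (an
#'       `activity_metrics` computed from the planted times, or `NULL` if
#'       no pulse was planted)}
#'     \item{config}{the configuration used}
#'   }
#' @examples
#' sim <- simulate_recording(synth_config(duration_s = 30, n_channels = 2,
#'                                        sample_rate_hz = 1000, seed = 7))
#' length(sim$truth$cp_times_s)
#' @export
simulate_recording <- function(config, params = detection_params()) {
  stopifnot(inherits(config, "synth_config"))
  params <- as_detection_params(params)
  with_seed(config$seed, {
    cfg <- config
    slow <- cfg$slowdown_factor
    dur <- cfg$duration_s

    # plant burst onsets and pulse times
    cp_times <- numeric(0)
    membership <- integer(0)
    if (cfg$burst_rate > 0) {
      mean_gap <- 60 / cfg$burst_rate * slow
      t_on <- rgamma_mean_cv(1, mean_gap, cfg$burst_interval_cv)
      b <- 0L
      while (t_on < dur) {
        b <- b + 1L
        n_p <- 1L + stats::rpois(1, max(cfg$peaks_per_burst - 1, 0))
        gaps <- if (n_p > 1L)
          rgamma_mean_cv(n_p - 1L, cfg$intra_burst_interval_s * slow,
                         cfg$intra_burst_cv)
        else numeric(0)
        pk <- t_on + c(0, cumsum(gaps))
        pk <- pk[pk < dur]
        cp_times <- c(cp_times, pk)
        membership <- c(membership, rep(b, length(pk)))
        t_next <- t_on + rgamma_mean_cv(1, mean_gap, cfg$burst_interval_cv)
        # bursts are serial behavioural episodes: the next one cannot begin
        # inside the previous burst
        if (length(pk))
          t_next <- max(t_next,
                        pk[length(pk)] + cfg$intra_burst_interval_s * slow)
        t_on <- t_next
      }
    }
    # bursts from a renewal process may interleave; keep truth in time order
    ord <- order(cp_times)
    cp_times <- cp_times[ord]
    membership <- membership[ord]
    if (length(cp_times) >= 2L && any(diff(cp_times) < 2 * cfg$cp_width_s)) {
      warning("planted events denser than the pulse template width: ",
              "overlapping waveforms merged in the ground truth")
      # two pulses closer than the template cannot be resolved as two events
      keep <- c(TRUE, diff(cp_times) >= 2 * cfg$cp_width_s)
      cp_times <- cp_times[keep]
      membership <- membership[keep]
    }
    if (length(cp_times) == 0L)
      warning("duration too short for a single burst: ground truth is empty")

    rp_times <- numeric(0)
    if (cfg$rp_amplitude > 0 && cfg$rp_rate_hz > 0) {
      n_rp <- stats::rpois(1, cfg$rp_rate_hz * dur / slow)
      rp_times <- sort(stats::runif(n_rp, 0, dur))
    }

    # render the noise-free waveform shared by all channels
    n_samp <- as.integer(round(dur * cfg$sample_rate_hz))
    tgrid <- (seq_len(n_samp) - 1) / cfg$sample_rate_hz
    clean <- numeric(n_samp)
    add_events <- function(sig, times, amp, width) {
      half <- as.integer(ceiling(6 * width * cfg$sample_rate_hz))
      for (tc in times) {
        ic <- as.integer(round(tc * cfg$sample_rate_hz)) + 1L
        lo <- max(1L, ic - half)
        hi <- min(n_samp, ic + half)
        if (lo > hi) next
        sig[lo:hi] <- sig[lo:hi] +
          amp * pulse_template(tgrid[lo:hi] - tc, width)
      }
      sig
    }
    clean <- add_events(clean, cp_times, cfg$cp_amplitude, cfg$cp_width_s)
    if (length(rp_times))
      clean <- add_events(clean, rp_times, cfg$rp_amplitude, cfg$cp_width_s)

    gains <- cfg$channel_gains
    if (is.null(gains))
      gains <- stats::rlnorm(cfg$n_channels, meanlog = 0, sdlog = 0.5)

    m <- matrix(0, nrow = cfg$n_channels, ncol = n_samp)
    for (ch in seq_len(cfg$n_channels)) {
      m[ch, ] <- gains[[ch]] * clean +
        if (cfg$noise_sigma > 0) stats::rnorm(n_samp, 0, cfg$noise_sigma)
        else 0
    }
    rec <- recording_set(m, sample_rate = cfg$sample_rate_hz,
                         source_id = sprintf("sim_seed%d", cfg$seed),
                         metadata = list(seed = cfg$seed))

    true_metrics <- NULL
    if (length(cp_times)) {
      rel <- cp_times - cp_times[[1L]]
      ev <- classify_intervals(rel, t_last = dur - cp_times[[1L]],
                               params = params,
                               source_id = rec$traces[[1L]]$source_id)
      true_metrics <- compute_metrics(ev)
    }

    structure(
      list(
        recording = rec,
        truth = list(
          cp_times_s = cp_times,
          burst_membership = membership,
          rp_times_s = rp_times,
          channel_gains = gains,
          true_metrics = true_metrics
        ),
        config = cfg
      ),
      class = "synth_recording"
    )
  })
}

#' @export
print.synth_recording <- function(x, ...) {
  cat(sprintf(
    "synth_recording: %d planted CPs in %d bursts (+%d RPs), seed %d\n",
    length(x$truth$cp_times_s),
    if (length(x$truth$burst_membership)) max(x$truth$burst_membership) else 0L,
    length(x$truth$rp_times_s), x$config$seed
  ))
  print(x$recording)
  invisible(x)
}

#' Analytic expectations implied by a simulator configuration
#'
#' Closed-form first-order expectations for the renewal-process burst
#' model, used to program scenarios and to check estimates against truth:
#' \describe{
#'   \item{hyai}{expected Hydra Activity Index. Per renewal cycle the
#'     contraction time is \eqn{(\bar n_p - 1)\, \bar\delta} (mean number
#'     of intra-burst intervals times their mean) and the elongation time
#'     is the rest of the mean cycle, so
#'     `hyai = c / (g - c)` with `c = (peaks_per_burst - 1) *
#'     intra_burst_interval_s` and `g = 60 / burst_rate`. Independent of
#'     `slowdown_factor`, which scales both.}
#'   \item{n_cp_mean}{expected planted pulse count over `duration_s`:
#'     number of cycles times mean pulses per burst.}
#'   \item{n_cp_cv}{asymptotic coefficient of variation of the pulse
#'     count, combining renewal-counting variance
#'     (\eqn{\mathrm{Var}\,B \approx E[B]\,cv_X^2}) with the Poisson
#'     per-burst variance.}
#' }
#'
#' @param config A [synth_config()].
#' @return A list with `hyai`, `n_cp_mean`, `n_cp_cv`.
#' @export
expected_activity <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  c_time <- (config$peaks_per_burst - 1) * config$intra_burst_interval_s
  g <- 60 / config$burst_rate
  if (c_time >= g)
    warning("mean burst span exceeds the mean inter-onset interval: ",
            "bursts overlap on average")
  lambda <- config$peaks_per_burst - 1       # Poisson part of pulses/burst
  e_b <- config$duration_s / (g * config$slowdown_factor)
  e_p <- 1 + lambda
  var_n <- e_b * lambda + config$burst_interval_cv^2 * e_b * e_p^2
  list(
    hyai = c_time / (g - c_time),
    n_cp_mean = e_b * e_p,
    n_cp_cv = sqrt(var_n) / (e_b * e_p)
  )
}

#' Build a simulator configuration with a programmed activity index
#'
#' Chooses the burst rate so that the expected Hydra Activity Index equals
#' `hyai`, holding the burst structure fixed: given the expected burst
#' span `c = (peaks_per_burst - 1) * intra_burst_interval_s`, the mean
#' inter-onset interval is set to `c * (1 + hyai) / hyai`.
#'
#' @param hyai Target expected activity index (> 0).
#' @param intra_burst_interval_s,peaks_per_burst Burst structure; the
#'   defaults give a compact burst (17 pulses 0.25 s apart, expected span
#'   4 s) whose span variance is small next to the quiet gap, so a
#'   classification threshold between the intra-burst interval and the
#'   gap separates the two interval populations cleanly even at an
#'   activity index of 1.
#' @param burst_interval_cv Dispersion of the inter-onset renewal process;
#'   kept low (0.1) for the same reason.
#' @param ... Further arguments passed to [synth_config()].
#' @return A [synth_config()] whose [expected_activity()]`$hyai` equals
#'   `hyai`.
#' @export
synth_config_hyai <- function(hyai, intra_burst_interval_s = 0.25,
                              peaks_per_burst = 17,
                              burst_interval_cv = 0.1, ...) {
  stopifnot(hyai > 0)
  c_time <- (peaks_per_burst - 1) * intra_burst_interval_s
  g <- c_time * (1 + hyai) / hyai
  synth_config(
    burst_rate = 60 / g,
    intra_burst_interval_s = intra_burst_interval_s,
    peaks_per_burst = peaks_per_burst,
    burst_interval_cv = burst_interval_cv,
    ...
  )
}
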