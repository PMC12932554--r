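# hycp — contraction-pulse sorting for whole-organism MEA recordings

`hycp` analyses extracellular multielectrode-array (MEA) recordings of
whole small organisms — the motivating preparation is *Hydra vulgaris* on
a 60-electrode array sampled at 10 kHz. Such recordings are dominated by
high-amplitude **contraction pulses (CPs)** that appear in rhythmic
**contraction bursts (CBs)**, separated by long **inter-contraction burst
intervals (IcBIs)** during which the animal elongates. Because every
electrode sees the same events with wildly different amplitudes
(electrode–tissue coupling varies), the pipeline classifies events by
their temporal and morphological features rather than absolute amplitude,
and analyses the single channel with the best signal-to-noise ratio.

It is aimed at electrophysiologists who want a scriptable, testable
alternative to vendor GUIs for burst-structured whole-animal signals, and
it ships a synthetic-signal simulator with ground truth so every stage of
the pipeline can be validated without access to original recordings.

## The method

For one selected channel with amplitude vector *S*:

1. **Normalise**: `Signal_norm(j) = S(j) / max|S|`, so detection
   thresholds are dimensionless.
2. **Smooth**: centred moving average over *N* samples (the *average
   threshold*, default *N* = 200, i.e. 20 ms at 10 kHz).
3. **Differentiate**: centred finite differences with step θ (the *time
   threshold*):
   `f′(tᵢ) = [x(tᵢ+θ/2) − x(tᵢ−θ/2)] / θ`, and `f″` by applying the same
   stencil to `f′` (deliberately, rather than the direct three-point
   second difference).
4. **Detect**: sample *i* is a peak iff the smoothed signal exceeds the
   *normalised threshold*, `f′ > 0` (rising edge), and `f″` changes sign
   from + to − within the ±θ/2 stencil (concavity transition at an apex).
   After each accepted peak the scan jumps past a *refractory period*.
5. **Align and window**: every recording is re-zeroed at its first peak
   and truncated to the common window `t_last = min(t_final − t_first)`
   across recordings.
6. **Classify intervals**: each inter-peak interval δ (plus the terminal
   interval to `t_last`) is a CP interval if δ < *CP threshold*, an IcBI
   if δ ≥ *IcBI threshold*; maximal runs of CP intervals form bursts.
7. **Metrics**: CPI durations, per-burst `BurstTime`, totals `CTime` and
   `ETime`, counts `nBurst`, `nCP`, `nIcBI`, `nCPBurst`, and the activity
   index

   `HyAI = Σ δ_CP / Σ δ_IcBI ≡ CTime / ETime`,

   the balance of contractile versus elongation behaviour. Reporting
   helpers add per-condition summaries (mean, SD, σ* = σ/|μ|, quartiles,
   5th/95th percentiles), Welch t-tests, and PCA over
   `{CTime, ETime, nBurst, nCP}`.

## Worked example

```r
library(hycp)

cfg <- synth_config(duration_s = 300, sample_rate_hz = 2000, n_channels = 8,
                    burst_rate = 2, peaks_per_burst = 4,
                    intra_burst_interval_s = 2, cp_width_s = 0.01,
                    noise_sigma = 0.08, seed = 42)
sim <- simulate_recording(cfg)
sim
#> synth_recording: 38 planted CPs in 8 bursts (+0 RPs), seed 42
#> recording_set: 8 channels x 600000 samples at 2000 Hz (300.000 s) [sim_seed42]

params <- detection_params(normalized_threshold = 0.3, average_window = 40,
                           time_threshold = 0.02, refractory_period = 0.5)
select_best_channel(sim$recording, snr_window = 40)
#> [1] 2          # the channel with the largest simulated gain

train <- analyze_recording(sim$recording, params)
train
#> cp_train: 38 peaks in 'sim_seed42' (channel 2), record length 300.000 s
#>   first peaks (s): 41.965, 44.477, 46.416, 61.724, 63.989, 65.534, 68.810, 89.825 ...

aligned <- align_trains(list(train))
events  <- classify_intervals(aligned$trains[[1]], aligned$t_last, params)
compute_metrics(events)
#> activity_metrics for 'recording' (window 258.034 s)
#>   CTime 57.870 s over 30 CP intervals; ETime 200.163 s over 8 IcBI
#>   8 burst(s); CPs per burst: 2 3 1 5 7 5 4 3
#>   HyAI = 0.2891
```

All 38 planted pulses are recovered; the detected train is re-zeroed at
its first peak (41.965 s of pre-peak signal discarded), the 258 s common
window splits into 57.9 s of contraction time and 200.2 s of elongation
time, and the resulting activity index 0.289 sits near the configured
duty cycle (`expected_activity(cfg)$hyai` = 0.25) up to burst-count
randomness in a 300-s window.

A thin CLI wraps the same functions
(`inst/cli/hycp <simulate|detect|metrics|raster|compare>` with a YAML
config); every output directory receives the archived effective
configuration for provenance.

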