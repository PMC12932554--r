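---
title: "Sorting contraction pulses in whole-organism MEA recordings"
author: "hycp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting contraction pulses in whole-organism MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hycp)
```

## The signal and the problem

A millimetre-sized animal resting on a planar MEA drives every electrode
with the same bioelectrical events, but at amplitudes that differ by an
order of magnitude from channel to channel, because the coupling between
tissue and each electrode is uneven and changes as the animal moves. The
events of interest are contraction pulses (CPs): large, brief, biphasic
field potentials generated by synchronous activity of large cell
populations, arriving in rhythmic groups (contraction bursts) separated
by long quiescent inter-contraction burst intervals (IcBIs) during which
the animal elongates. Low-amplitude rhythmic potentials (RPs) can appear
between bursts when coupling is good.

Two consequences shape the design:

* absolute amplitude is unreliable, so events are recognised by
  *temporal and morphological* features — a thresholded, smoothed,
  normalised trace plus first- and second-derivative criteria;
* averaging channels would dilute low-amplitude events below any fixed
  threshold, so a *single* channel — the one with the best
  signal-to-noise ratio — is analysed per recording.

## Pipeline and model assumptions

Given the amplitude vector $S$ of the selected channel:

$$\mathrm{Signal_{norm}}(j) = \frac{S(j)}{\max_j |S(j)|}, \qquad
\mathrm{Signal_{mean}}(i) = \frac{1}{N}\sum_{k \in w_N(i)} \mathrm{Signal_{norm}}(k)$$

with $w_N(i)$ a centred window of $N$ samples (the *average threshold*).
Derivatives use the centred finite difference with step $\theta$ (the
*time threshold*):

$$f'(t_i) = \frac{x(t_i + \theta/2) - x(t_i - \theta/2)}{\theta}, \qquad
f''(t_i) = \frac{f'(t_i + \theta/2) - f'(t_i - \theta/2)}{\theta}.$$

$f''$ is deliberately the *composition* of two first-difference stencils
rather than the direct three-point second difference: it is somewhat
more noise-sensitive, but sharpens the curvature transitions that mark
genuine pulse apices. Both operators are exact on affine (first) and
quadratic (composed second) signals, which the test suite asserts, and
second-order accurate otherwise.

A sample is accepted as a peak iff, jointly, (i) the smoothed signal
exceeds the *normalised threshold*, (ii) $f' > 0$, and (iii) $f''$
crosses from positive to non-positive within the $\pm\theta/2$ stencil.
After acceptance the scan pointer jumps past the *refractory period*, so
one waveform can never yield two detections. Detection assumes the pulse
is the dominant transient at the 10-ms-to-100-ms scale after smoothing;
it does not assume anything about polarity of the raw trace because
normalisation uses the absolute maximum.

Event analysis assumes recordings are comparable only after removing the
arbitrary pre-first-peak interval: trains are re-zeroed at their first
peak and truncated to the common window $t_{last}$, the minimum aligned
length. Inter-peak intervals (including the terminal interval up to
$t_{last}$) are classified by duration alone: below the *CP threshold*
they are contraction-pulse intervals, at or above the *IcBI threshold*
they are inter-burst intervals. Bursts are maximal runs of CP intervals.
The activity index $\mathrm{HyAI} = C_{time}/E_{time}$ then summarises
the contraction/elongation balance; it is undefined (flagged, reported
as infinite) when no IcBI exists in the window.

## Parameters

| parameter | units | default | role |
|---|---|---|---|
| `normalized_threshold` | – (fraction of max amplitude) | 0.3 | amplitude gate on the smoothed trace |
| `average_window` | samples | 200 (20 ms at 10 kHz) | noise smoothing; must stay well below pulse spacing |
| `time_threshold` θ | s | 0.02 | derivative step; the stencil spans ±θ/2 |
| `refractory_period` | s | 1.0 | detector dead time; below the fastest credible CP rate |
| `cp_threshold` | s | 10 | intervals shorter than this are burst components |
| `icbi_threshold` | s | 10 (= `cp_threshold`) | intervals at/above this are inter-burst |

The defaults are working values for spontaneously active *Hydra*: CPs
within a burst arrive seconds apart, bursts recur on the minute scale,
so a 10 s interval threshold splits the two populations cleanly. They
are deliberately conservative, exposed in `detection_params()` and in
the CLI YAML config, and should be tuned per preparation — device
geometry alone changes pulse width and rate substantially.

Numerical conventions that the equations leave open were fixed once:

* **Normalisation by $\max|S|$**, not the signed maximum: extracellular
  deflections can be negative-dominant and a signed maximum would flip
  polarity. For positive-dominant traces the two coincide.
* **Even windows**: a centred window of even length $N$ is realised as
  $[j - N/2,\ j + N/2 - 1]$; at the edges the window is truncated to the
  available samples (no padding, so no phantom values bias the mean).
* **Grid alignment of θ**: $\theta/2$ must land exactly on the sample
  grid (θ an even number ≥ 2 of sample intervals); anything else is a
  parameter error rather than a silent interpolation.
* **Concavity transition**: read as a + → − sign change of $f''$, the
  only direction consistent with a peak apex; it is searched within the
  ±θ/2 stencil of the candidate sample, which makes the criterion robust
  to the exact sample on which the noisy $f''$ crosses zero.
* **Peak time**: the accepted sample's own timestamp. No sub-sample
  interpolation; at 10 kHz the grid error (0.1 ms) is negligible against
  pulse width.
* **Terminal interval**: taken as the non-negative duration
  $t_{last} - t_{p_{last}}$ and classified by the same rule as interior
  intervals.
* **Degenerate inputs**: identically-zero traces, all-constant channel
  sets, empty trains and windows shorter than the stencil raise typed
  errors early; a recording whose elongation time is zero yields a
  flagged, not thrown, activity index.

Two bookkeeping conventions are configurable because the field uses
both. `nCPBurst` counts CP-classified *intervals* per burst by default
(so `nCP = Σ nCPBurst` and `CTime = Σ CPI` are mutually consistent); a
`peaks` convention counting the bounding peaks (one more per burst) is a
switch. Bursts are counted as maximal CP runs; incrementing on each IcBI
instead undercounts by one when a recording ends inside a burst, so the
IcBI count is reported separately. If `cp_threshold < icbi_threshold`,
intervals between them are labelled `ambiguous`, excluded from bursts
and from $C_{time}/E_{time}$, and warned about; the default keeps the
thresholds equal so the classification is a binary split.

## The synthetic-data generator

`simulate_recording()` emulates the phenomenology the detector targets:

* burst onsets from a gamma renewal process (`burst_rate` per minute,
  dispersion `burst_interval_cv`); bursts are serial behavioural
  episodes, so an onset is deferred until at least one intra-burst
  interval after the previous burst ends;
* $1 + \mathrm{Poisson}$ pulses per burst, gamma intra-burst intervals;
* each pulse a biphasic difference-of-Gaussians template (widths
  $\sigma$ and $2\sigma$), the centre-surround shape of an extracellular
  field potential, apex-normalised and scaled by `cp_amplitude`;
* channel-synchronous timing with per-channel log-normal gains (the
  amplitude inconsistency that motivates SNR-based channel selection),
  plus independent white Gaussian noise per channel;
* optional low-amplitude RP train (generated but never detected — it
  serves as structured interference in robustness tests);
* `slowdown_factor` multiplying every sampled interval, an
  anaesthesia-like rate slowdown scenario;
* full ground truth (pulse times, burst membership, implied metrics)
  carried in memory and in the HDF5 output, bit-reproducible per seed.

What it does **not** model: electrode impedance and coupling drift,
waveform shape variability and amplitude adaptation within bursts,
correlated (movement) noise, line interference, and amplitude summation
of overlapping pulses — two planted pulses closer than the template
width are merged into one ground-truth event, with a warning. Passing
tests on this generator therefore demonstrate correctness of the
*algorithmic* chain under its stated assumptions, not performance on any
particular laboratory's recordings.

Default generator values (one burst per minute, five pulses per burst a
few seconds apart, 10 ms templates, noise σ = 0.05 of the pulse
amplitude, 60 channels at 10 kHz) were chosen once as a realistic
spontaneous-activity regime for this preparation and are not tuned per
test.

## Validation-scenario design

The test-suite scenarios scale sizes to what the properties need, not
more: detector precision/recall uses 60-s single-channel recordings at
the native 10 kHz (100 seeds); interval bookkeeping and the brute-force
classification oracle use 200 random abstract trains; activity-index
recovery and the slowdown scenario use 600-s recordings at 1 kHz with a
20-sample smoothing window — the same 20 ms of smoothing at a tenth the
grid cost. Two scenario choices deserve a note:

* **Resolvable ground truth.** Recovery scenarios use an intra-burst
  dispersion (cv 0.2 at 2 s mean) under which the probability of two
  planted pulses falling within the 0.3 s refractory period is
  negligible (~1e-13). A ground-truth pair closer than the detector's
  dead time is undetectable *by construction*, so recall against it
  would measure the scenario, not the detector.
* **Separable interval populations.** The programmed-activity scenarios
  use compact bursts (17 pulses, 0.25 s apart, ≈ 4 s span) and low
  renewal dispersion so that a 1.5 s interval threshold sits many
  standard deviations from both the intra-burst and the inter-burst
  interval distributions, even at an activity index of 1. The
  programmed index follows from the renewal model:
  $\mathrm{HyAI} = c/(g - c)$ for mean burst span $c$ and mean
  inter-onset interval $g$ (`expected_activity()`), which
  `synth_config_hyai()` inverts.

## Known limitations

* Detection timestamps sit on the rising edge a few milliseconds before
  the waveform apex (the concavity transition precedes the maximum); for
  interval *durations* this bias cancels between consecutive peaks.
* The second-derivative criterion is noise-sensitive by design; at very
  low SNR (noise beyond ~1/5 of pulse amplitude after smoothing) the
  threshold condition dominates and detection degrades gracefully to
  threshold crossing.
* Channel selection maximises a peak-to-peak/robust-noise score; a
  channel with large movement artefacts can outscore a cleaner one. The
  scorer is pluggable (`select_best_channel(scorer = ...)`) and an
  explicit `--channel` override exists in the CLI.
* RPs are simulated but no RP detector is provided; intervals are
  classified purely by duration, with no physiological attribution.
* The vendor HDF5 reader covers only the common nested dataset path as
  a best effort; the documented native dialect is the supported format.
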