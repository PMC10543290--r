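---
title: "Methods: EEG and HD-MEA phenotyping of mouse models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG and HD-MEA phenotyping of mouse models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephyspheno)
```

# Scope

`ephyspheno` quantifies the neurophysiological phenotype of a mutant mouse
line on two levels: *in vivo*, from wireless EEG/EMG telemetry (spectral
band power, epileptiform spike trains, four-state sleep architecture), and
*in vitro*, from high-density microelectrode array (HD-MEA) recordings of
cultured primary neurons (network bursts across days in vitro). Because
such studies rarely deposit raw recordings, the package carries a
synthetic-data generator whose output has the same container types and
known ground truth, so every analysis stage is validated end to end before
it ever touches animal data.

# Signal model and containers

A telemetry record is EEG and EMG in microvolts at 500 Hz (acquisition
band-pass 0.1–100 Hz) plus a locomotor activity trace at 200 Hz
(`signal_recording`). An HD-MEA record is an event list of
(electrode id, spike time) pairs over a 26,400-electrode chip
(`spike_raster`). All times are seconds from recording start; electrode
ids are 0-based. EDF is the interchange format for continuous signals —
it quantizes to 16 bits over a per-channel symmetric physical range, so a
round trip is exact in sample counts and rates and accurate to half a
quantization step in amplitude. Rasters travel as a CSV event list with a
JSON metadata sidecar, chosen over a binary container so that desk-scale
inspection needs no tooling.

# Spectral analysis

The PSD estimator is Welch's method: Hann-tapered segments (default 2 s,
50% overlap), per-segment periodograms averaged, one-sided density scaling
such that integrating the PSD over frequency recovers the signal variance.
Absolute band power is the trapezoidal integral of the PSD over the band.
The default bands keep the study's printed definitions verbatim — delta
0.5–4 Hz, theta 5–9 Hz (the 4–5 Hz gap included), alpha 9–12, beta 12–30,
gamma 30–100 Hz. Adjacent bands sharing an edge each receive half of the
edge bin under the trapezoid rule, so disjoint bands never double count
and their sum never exceeds the total power.

Two numerical points matter in practice:

* **Resolution vs. band width.** The 2 s default window gives 0.5 Hz
  resolution, enough to resolve the 0.5 Hz delta edge. For a *narrow* band
  (e.g. integrating a 1 Hz-wide band around a tone) the Hann main lobe
  spans ±2 bins; with 0.5 Hz bins the lobe fills the whole band and the
  trapezoid's half-weighted edges drop ~17% of the tone's power. Checks
  that integrate bands comparable in width to the main lobe therefore use
  a 4 s window (0.25 Hz bins), which recovers a tone's analytic power
  A²/2 to well under 1%. This is a property of any fixed-taper estimator,
  not of this implementation.
* **Artifact rejection.** Segments whose RMS exceeds 6× the median segment
  RMS are dropped from the Welch average (count reported in the result).
  The source study is silent on artifact handling; this conservative rule
  protects multi-hour averages from electrode artifacts and can be
  disabled (`artifact_rms_factor = Inf`).

# Epileptiform spikes and spike trains

Spikes are local extrema of the 1–70 Hz band-passed EEG whose absolute
amplitude exceeds `threshold_sd` (default 5) times a robust baseline
scale, defined as 1.4826 × the median absolute deviation of the filtered
signal — the MAD-based scale keeps the spikes themselves from inflating
the threshold, which a plain SD would do at high spike rates. Events
closer than a 50 ms refractory window keep only the largest. Trains are
single-linkage clusters in time: consecutive spikes with gaps ≤ 2 s join,
clusters with fewer than 3 spikes are discarded, and train duration is
last-minus-first spike time. The underlying clinical scoring conventions
are not printed in the source literature, so all four parameters are
declared, documented defaults rather than inferred values. At these
defaults a 5×MAD threshold crosses noise roughly once per 10–20 minutes
of clean recording; such isolated events are removed by the
`min_spikes = 3` rule, which is why train-level counts are stable where
raw spike counts are not.

# Sleep staging

Each 10 s epoch yields delta power, theta power, their ratio, EMG RMS and
mean activity; rules applied in order label it ACTIVE_WAKE (high EMG and
movement), WAKE (high EMG only), PARADOXICAL (low EMG, theta/delta
ratio > 1.5) or SWS (otherwise). The epoch length is configurable; 10 s is
the package default since the source study does not state one (a related
rat study used 5 s epochs without EMG).

Thresholds are per-recording, for scale invariance across implants. The
EMG threshold default is the midpoint (on the log scale) between the two
clusters found by 2-means on epoch EMG RMS. A fixed-percentile rule (the
obvious alternative, retained as `emg_threshold = "p60"`) mislabels
approximately |realized wake fraction − implied split| of all epochs
whenever a recording's wake occupancy drifts from the percentile's implied
split — with 180 epochs and a sticky state sequence, occupancy routinely
drifts by ±7% — whereas the cluster midpoint tracks the bimodal EMG
distribution itself. The activity threshold is the recording's noise floor
(median + 10 × MAD of epoch mean activity): W and sleeping epochs carry
no locomotion, so any genuine movement clears it by an order of magnitude.
The scorer is deterministic given features and thresholds, and no
smoothing is applied by default (3-epoch majority smoothing is available
but biases brief-state percentages).

# HD-MEA network bursts

The activity scan computes each electrode's firing rate over the first
30 s; the network stage pools the 1024 highest-rate electrodes (ties
broken by ascending id, deterministically). Pooled spike times are binned
at `dt` = 10 ms and convolved with a unit-area Gaussian kernel
(σ = 50 ms, truncated at ±4σ), so the trace integrates to the pooled
spike count to within 0.1%. The study names Gaussian convolution but no
kernel width; 50 ms resolves bursts a few hundred ms long while smoothing
over the Poisson granularity of background firing.

Bursts are contiguous regions above `baseline + k × spread` (baseline =
trace median, spread = scaled MAD, k = 5, with a floor of 2× baseline —
median/MAD rather than mean/SD so that burst-dominated traces do not
raise their own threshold). Each candidate extends outward to the 10%-of-
peak-height crossing, candidates with peaks closer than 0.2 s merge, and
the inter-burst interval is **peak-to-peak**, matching the phenotype's
"interval between peaks" convention rather than offset-to-onset. Burst
statistics are per chip, the analysis unit of the longitudinal figures.

# The synthetic generator

The EEG generator draws a per-epoch vigilance state from a four-state
Markov chain, then mixes three unit-variance processes per epoch: 0.5–4 Hz
and 5–9 Hz band-limited noise (4th-order Butterworth on white noise) and a
1/f (exponent 1.0) broadband background, each scaled by the state's
amplitude (µV); EMG is white noise at the state's RMS and activity is the
state's level plus noise, floored at zero. Transition matrices are built
as ρI + (1−ρ)·1πᵀ, which has stationary distribution exactly π with
dwell controlled by ρ (default 0.5–0.6). Epileptiform events are biphasic
40 ms transients (one positive, one negative lobe) in trains with 0.2 s
intra-train gaps, placed either as a Poisson count or as an exact planted
count for recovery testing; placements are slotted with a guard separation
so planted trains never merge. The MEA generator fires a configurable
subset of electrodes as homogeneous Poisson processes and superimposes
synchronized bursts in which each participating electrode multiplies its
rate for the burst duration; burst onsets follow a thinned Poisson process
(exponential gaps on top of a guard interval) so ground-truth windows
never overlap.

The WT/HET presets encode the mutant phenotype's *directions*: higher
delta/theta amplitudes, three-fold spike-train rate with longer trains,
occupancy shifted from SWS (45% → 36%) toward active wake (15% → 30%),
and cultures that burst twice as often with fewer spikes per burst.
Occupancy gaps are sized so the per-subject effect sizes match the large
reported group statistics (d ≈ 1.4–1.7); all magnitudes are illustrative
defaults, configurable, since the source reports no effect sizes for
these quantities. What the generator does *not* emulate: circadian
(light/dark) modulation, electrode artifacts and implant drift, seizure
morphologies beyond spike trains, non-stationary culture dynamics within
a recording, and spatial structure on the chip. Passing recovery tests on
this generator therefore demonstrates correctness of the *analysis*
under the stated signal model, not robustness to every failure mode of
real telemetry.

# Statistical layer

Group contrasts follow the source study's conventions: a single-pass 2-SD
inclusion filter per group (mean and SD computed once on the full group,
no re-iteration — at small n the filter cannot exclude a lone extreme
value, a documented weakness, not a bug), pooled-variance two-tailed
Student t tests (the study asserts similar variances), two-way ANOVA via
`stats::aov` with an `Error(id/within)` stratum for the repeated-measures
variant, and Sidak (1−(1−p)^m), Holm–Sidak (step-down with monotonicity)
and Bonferroni–Dunn (min(1, mp)) post hoc adjustments. α = 0.05
throughout; sexes pooled (no sex factor).

# Validation problem sizes

The test suite validates at sizes chosen to give tight Monte-Carlo
precision while remaining desk-scale: 30-minute telemetry records (180
epochs) over 20 seeds for staging recovery; 10 seeds × {0, 5, 20} planted
trains for spike recovery; 20 default 300 s × 1024-electrode rasters for
burst precision/recall and interval recovery; 10,000 and 1,000 null
replicates for t and F calibration. The two-hour stationary-occupancy
check uses the effective-sample-size correction n(1−ρ)/(1+ρ) for a sticky
chain. On these conditions the pipeline attains 100% staging agreement,
exact planted-train counts, burst precision 1.0 and recall ≥ 0.99; the
figures the package's own acceptance script recomputes are the ones
reported, never transcribed.

# Known limitations

* EDF writing uses 1 s records, so recordings must be whole seconds.
* The rule-based sleep scorer realizes the study's qualitative state
  definitions; absent printed thresholds, agreement with a human scorer
  on real telemetry is unverified (and unverifiable without that data).
* Spikes-per-burst is pooled across selected electrodes; a per-electrode
  variant is a one-line division but the pooled convention is primary.
* The 2-SD filter and pooled t test are reproduced as specified even
  where a statistician might prefer robust or Welch variants.
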