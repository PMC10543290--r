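# ephyspheno

Neurophysiological phenotyping of mouse models from EEG telemetry and
high-density microelectrode arrays (HD-MEA), built for studies of
neurodevelopmental-disorder genes (e.g. *Syngap1* haploinsufficiency)
where the phenotype spans *in vivo* brain activity and *in vitro* network
activity of cultured neurons.

The pipeline quantifies, per subject or chip:

* **Spectral band power** — Welch PSD (Hann window, 2 s segments, 50%
  overlap, density scaling so that ∫S(f)df = Var[x]) integrated over
  delta (0.5–4 Hz), theta (5–9 Hz), alpha, beta and gamma;
* **Epileptiform spike trains** — local extrema of the 1–70 Hz band-passed
  EEG above 5 × 1.4826·MAD, clustered single-linkage with gap ≤ 2 s and
  ≥ 3 spikes per train;
* **Four-state sleep architecture** — 10 s epochs labelled active wake /
  wake / slow-wave sleep / paradoxical sleep from EMG tone, locomotor
  activity and the theta/delta power ratio;
* **Network bursts** — 30 s activity scan over all 26,400 electrodes,
  selection of the 1024 highest-firing, Gaussian-smoothed (σ = 50 ms)
  population rate r(t) with ∫r dt = spike count, bursts as regions above
  median + 5·MAD (floor 2 × median), inter-burst interval peak-to-peak;
* **Group statistics** — single-pass 2-SD inclusion filter, pooled-variance
  two-tailed t tests, two-way (genotype × DIV) ANOVA with Sidak /
  Holm–Sidak / Bonferroni–Dunn post hocs.

A seeded synthetic-data generator (Markov sleep architecture, per-state
band-limited + 1/f EEG mixtures, biphasic spike transients, Poisson
background firing with synchronized bursts) provides ground truth for
every stage, with `WT`/`HET` presets encoding the mutant phenotype's
directions. See `vignettes/ephys-phenotyping-methods.Rmd` for the models
and all parameter rationale.

## Worked example

The `analysis/` directory is the study workflow: numbered scripts that
simulate the cohorts (`01`), then run each stage and write its tables
under `results/`. Running them in order prints, for a cohort of 6 WT vs 6
HET telemetry subjects (30 min each) and 6 chips/genotype across DIV
17–35:

```
$ Rscript analysis/02_eeg_spectral.R
delta band power: WT 965 uV^2, HET 1315 uV^2 (HET/WT = 1.36)
theta band power: WT 483 uV^2, HET 882 uV^2 (HET/WT = 1.83)

$ Rscript analysis/03_spike_trains.R
spike trains / 30 min: WT 1.7, HET 9.5
mean train duration:   WT 0.58 s, HET 1.23 s
detection vs planted:  11 of 12 subjects exact

$ Rscript analysis/04_sleep_staging.R
staging agreement vs ground truth: mean 100.0%, min 100.0%
percent_active_wake    WT  16.0%  HET  31.2%
percent_sws            WT  44.0%  HET  30.0%

$ Rscript analysis/05_mea_bursts.R
DIV21 inter-burst interval: WT  35.6 s, HET  19.1 s
DIV29 inter-burst interval: WT  26.9 s, HET  12.2 s
```

Read: the mutant cohort shows elevated delta/theta power, more and longer
spike trains, more active wake at the expense of slow-wave sleep, and —
in culture — bursts arriving roughly twice as often from DIV21 on. These
are the phenotype directions the presets encode; `06_group_stats.R` then
applies the statistical layer (t tests, genotype × DIV ANOVA,
Sidak-adjusted per-DIV contrasts) to those tables.

Equivalent programmatic entry points: `run_eeg_pipeline()` and
`run_mea_pipeline()` accept either recordings/rasters or a cohort
data.frame of (id, group, seed) and return metrics, comparisons and a
reproducibility manifest.

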