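Package: ephyspheno
Title: Neurophysiological Phenotyping of Rodent EEG Telemetry and HD-MEA Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for neurophysiological phenotyping of mouse
    models of neurodevelopmental disorders. Computes Welch power spectral
    densities and absolute band powers (delta, theta and above) from EEG
    telemetry, detects epileptiform spikes and groups them into spike trains,
    scores four vigilance states (active wake, wake, slow-wave sleep,
    paradoxical sleep) from EEG band power, EMG tone and locomotor activity,
    and quantifies network bursts on high-density microelectrode arrays via
    Gaussian-smoothed population firing rates. Includes a synthetic-data
    generator with genotype-styled wild-type and mutant presets so every stage
    can be validated against ground truth, plus the group-statistics layer
    (2-SD inclusion filter, pooled t tests, two-way ANOVA with Sidak-family
    post hocs) used to compare genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
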