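# Genotype-styled simulation presets. "HET" differs from "WT" in the
# directions reported for the mutant phenotype: elevated delta/theta EEG
# amplitudes, more and longer epileptiform spike trains, sleep architecture
# shifted toward active wake and away from slow-wave sleep, and cultures
# that burst more often (shorter inter-burst intervals) with fewer spikes
# per burst. Effect sizes are illustrative defaults, not fitted values.

preset_stationary <- list(
  WT  = c(ACTIVE_WAKE = 0.15, WAKE = 0.25, SWS = 0.45, PARADOXICAL = 0.15),
  HET = c(ACTIVE_WAKE = 0.30, WAKE = 0.21, SWS = 0.36, PARADOXICAL = 0.13)
)

#' Simulation presets for a genotype
#'
#' Deterministic: the same name always yields identical configurations (the
#' rng seed is left NULL for the caller to set per subject/chip). The
#' optional `div` argument scales the MEA config with culture maturation so
#' longitudinal (DIV 17-35) cohorts can be simulated.
#'
#' @param name "WT" or "HET".
#' @param div optional day in vitro for the MEA preset.
#' @return list with elements `eeg` (an [eeg_sim_config()]) and `mea`
#'   (an [mea_sim_config()]).
#' @export
genotype_preset <- function(name = c("WT", "HET"), div = NULL) {
  if (!is.character(name) || !name[1] %in% c("WT", "HET"))
    stop("unknown preset name: ", name[1])
  name <- name[1]
  het <- name == "HET"

  prof <- default_state_profile()
  if (het) {
    prof$delta_amp <- prof$delta_amp * 1.4
    prof$theta_amp <- prof$theta_amp * 1.25
  }
  eeg <- eeg_sim_config(
    duration_s = 1800, epoch_len_s = 10,
    state_transition_matrix =
      sticky_transition_matrix(preset_stationary[[name]], stickiness = 0.5),
    state_profile = prof,
    spike_train_rate_per_hour = if (het) 15 else 5,
    spikes_per_train_range = if (het) c(5L, 10L) else c(3L, 6L),
    intra_train_gap_s = 0.2,
    spike_amplitude_uV = if (het) 400 else 300
  )

  # maturation factor: cultures burst little before ~DIV14, plateau ~DIV29
  mat <- if (is.null(div)) 1 else max(0.1, min(1, (div - 11) / 18))
  mea <- mea_sim_config(
    n_electrodes = 26400L, n_active_electrodes = 1024L, duration_s = 300,
    baseline_rate_hz = 1,
    burst_rate_per_min = (if (het) 5 else 2.5) * mat,
    burst_duration_s = 0.3,
    within_burst_rate_multiplier = (if (het) 12 else 20) * mat,
    electrode_participation_prob = 0.6
  )
  list(eeg = eeg, mea = mea)
}
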