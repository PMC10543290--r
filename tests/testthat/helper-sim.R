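# Shared fixture builders. All synthetic, generated at test time.

# flat-spectrum EEG background with planted spike trains, no state structure
flat_eeg_config <- function(duration_s, n_trains, amp = 200, seed = 1,
                            spikes_range = c(4L, 6L)) {
  prof <- default_state_profile()
  prof$delta_amp <- rep(0, 4)
  prof$theta_amp <- rep(0, 4)
  prof$broadband_amp <- rep(20, 4)
  eeg_sim_config(
    duration_s = duration_s, n_spike_trains = n_trains,
    spikes_per_train_range = spikes_range,
    spike_amplitude_uV = amp, state_profile = prof, rng_seed = seed
  )
}

# trapezoidal integral of a power_spectrum over its full support
psd_total <- function(sp) {
  sum(diff(sp$freqs_hz) * (head(sp$psd, -1) + tail(sp$psd, -1)) / 2)
}

# independent connected-component clustering of spike times: transitive
# closure of |ti - tj| <= max_gap over all pairs (quadratic, oracle only)
oracle_cluster <- function(times, max_gap) {
  n <- length(times)
  if (!n) return(integer(0))
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (abs(times[i] - times[j]) <= max_gap && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# greedy one-to-one matching of detected to true burst peaks
match_bursts <- function(detected, truth, tol_s) {
  used <- rep(FALSE, nrow(truth))
  hits <- 0
  for (p in detected) {
    d <- abs(truth$peak_s - p)
    d[used] <- Inf
    if (length(d) && min(d) <= tol_s) {
      used[which.min(d)] <- TRUE
      hits <- hits + 1
    }
  }
  hits
}
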