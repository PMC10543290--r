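# Synthetic EEG/EMG/activity generator. A per-epoch Markov chain draws the
# vigilance state; each state contributes band-limited delta (0.5-4 Hz) and
# theta (5-9 Hz) oscillations over a 1/f broadband background, an EMG tone and
# an activity level. Epileptiform spike trains (clusters of biphasic 40 ms
# transients) are superimposed and recorded as ground truth.

#' Default per-state signal profile
#'
#' Amplitudes (uV) of the delta, theta and 1/f broadband EEG components,
#' the EMG RMS and the activity level for each vigilance state. Slow-wave
#' sleep is delta-dominant, paradoxical sleep theta-dominant with atonia,
#' and only active wake carries locomotor activity.
#'
#' @return data.frame with one row per state (in [SLEEP_STATES] order).
#' @export
default_state_profile <- function() {
  data.frame(
    row.names = SLEEP_STATES,
    delta_amp     = c(10, 12, 45,  8),
    theta_amp     = c(25, 22, 10, 40),
    broadband_amp = c(15, 15, 15, 15),
    emg_rms       = c(30, 28,  6,  4),
    activity_level = c(8, 0, 0, 0)
  )
}

#' Sticky transition matrix with a prescribed stationary distribution
#'
#' P = stickiness * I + (1 - stickiness) * 1 pi', which is row-stochastic
#' with stationary distribution exactly `stationary`; higher stickiness
#' lengthens state dwell without changing occupancy.
#'
#' @param stationary length-4 probability vector over [SLEEP_STATES].
#' @param stickiness self-transition weight in [0, 1).
#' @return 4x4 row-stochastic matrix.
#' @export
sticky_transition_matrix <- function(stationary, stickiness = 0.6) {
  stopifnot(length(stationary) == 4, abs(sum(stationary) - 1) < 1e-9,
            stickiness >= 0, stickiness < 1)
  P <- stickiness * diag(4) +
    (1 - stickiness) * matrix(stationary, 4, 4, byrow = TRUE)
  dimnames(P) <- list(SLEEP_STATES, SLEEP_STATES)
  P
}

#' Stationary distribution of a transition matrix
#'
#' @param P row-stochastic matrix.
#' @return probability vector (left eigenvector of eigenvalue 1).
#' @export
markov_stationary <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Configuration for the synthetic EEG generator
#'
#' @param duration_s recording length (s); must be a multiple of
#'   `epoch_len_s`.
#' @param epoch_len_s sleep-scoring epoch length (s); state dwell is
#'   epoch-granular.
#' @param state_transition_matrix 4x4 row-stochastic matrix over
#'   [SLEEP_STATES] (rows = from-state).
#' @param state_profile data.frame with one row per state and columns
#'   `delta_amp`, `theta_amp`, `broadband_amp` (uV), `emg_rms` (uV),
#'   `activity_level` (a.u.).
#' @param spike_train_rate_per_hour Poisson rate of injected spike trains.
#' @param n_spike_trains exact number of trains to plant (overrides the rate;
#'   NULL for Poisson placement).
#' @param spikes_per_train_range integer pair, inclusive range of spikes per
#'   train.
#' @param intra_train_gap_s gap between consecutive spikes within a train (s).
#' @param spike_amplitude_uV peak amplitude of each biphasic transient (uV).
#' @param eeg_rate_hz,activity_rate_hz channel sampling rates (Hz).
#' @param activity_noise_sd additive Gaussian noise on the activity trace.
#' @param rng_seed integer seed; fixed seed gives bit-identical output.
#' @return A list of class `eeg_sim_config`.
#' @export
eeg_sim_config <- function(duration_s = 1800, epoch_len_s = 10,
                           state_transition_matrix =
                             sticky_transition_matrix(c(0.15, 0.25, 0.45, 0.15)),
                           state_profile = default_state_profile(),
                           spike_train_rate_per_hour = 5,
                           n_spike_trains = NULL,
                           spikes_per_train_range = c(3L, 6L),
                           intra_train_gap_s = 0.2,
                           spike_amplitude_uV = 300,
                           eeg_rate_hz = 500, activity_rate_hz = 200,
                           activity_noise_sd = 0.2,
                           rng_seed = NULL) {
  P <- as.matrix(state_transition_matrix)
  if (!all(dim(P) == c(4, 4)) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-9))
    stop("state_transition_matrix must be 4x4 row-stochastic (rows sum to 1)")
  if (duration_s <= 0 || epoch_len_s <= 0 ||
      abs(duration_s / epoch_len_s - round(duration_s / epoch_len_s)) > 1e-9)
    stop("epoch_len_s must divide duration_s")
  if (!all(rownames(state_profile) == SLEEP_STATES))
    stop("state_profile rows must be the four sleep states, in order")
  if (any(as.matrix(state_profile) < 0)) stop("all amplitudes must be >= 0")
  if (spike_train_rate_per_hour < 0 || spike_amplitude_uV < 0 ||
      intra_train_gap_s < 0)
    stop("spike-train parameters must be >= 0")
  structure(list(
    duration_s = duration_s, epoch_len_s = epoch_len_s,
    state_transition_matrix = P, state_profile = state_profile,
    spike_train_rate_per_hour = spike_train_rate_per_hour,
    n_spike_trains = n_spike_trains,
    spikes_per_train_range = as.integer(spikes_per_train_range),
    intra_train_gap_s = intra_train_gap_s,
    spike_amplitude_uV = spike_amplitude_uV,
    eeg_rate_hz = eeg_rate_hz, activity_rate_hz = activity_rate_hz,
    activity_noise_sd = activity_noise_sd, rng_seed = rng_seed
  ), class = "eeg_sim_config")
}

# Biphasic transient: one positive then one negative lobe, `width_s` total,
# unit peak; returned sampled at fs and centred so the positive peak is at
# sample round(width_s/4 * fs).
spike_waveform <- function(fs, width_s = 0.04) {
  t <- seq(0, width_s, by = 1 / fs)
  sin(2 * pi * t / width_s)
}

# Place `k` train onsets in [margin, duration - margin - train_len] with
# pairwise separation >= min_sep, by jittered slotting (deterministic count).
place_trains <- function(k, duration_s, train_len, min_sep, margin = 2) {
  if (k == 0) return(numeric(0))
  usable <- duration_s - 2 * margin - train_len
  slot <- usable / k
  if (slot < train_len + min_sep)
    stop("recording too short to place ", k, " non-overlapping spike trains")
  jit <- stats::runif(k, 0, max(0, slot - train_len - min_sep))
  margin + (seq_len(k) - 1) * slot + jit
}

#' Simulate a telemetry recording with known ground truth
#'
#' @param config an [eeg_sim_config()].
#' @param subject_id,group_label metadata for the resulting recording.
#' @return A list with elements `recording` (a [signal_recording()]) and
#'   `truth` (list: `hypnogram`, `spike_trains` data.frame with
#'   onset_s/offset_s/n_spikes).
#' @export
simulate_eeg <- function(config, subject_id = "sim", group_label = "WT") {
  stopifnot(inherits(config, "eeg_sim_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  fs <- config$eeg_rate_hz
  n <- round(config$duration_s * fs)
  n_act <- round(config$duration_s * config$activity_rate_hz)
  n_epochs <- round(config$duration_s / config$epoch_len_s)
  spe <- round(config$epoch_len_s * fs)            # samples per epoch (EEG)
  spe_act <- round(config$epoch_len_s * config$activity_rate_hz)

  # hypnogram: start at the stationary distribution, then iterate
  P <- config$state_transition_matrix
  pi0 <- markov_stationary(P)
  states <- integer(n_epochs)
  states[1] <- sample.int(4, 1, prob = pi0)
  if (n_epochs > 1)
    for (i in 2:n_epochs) states[i] <- sample.int(4, 1, prob = P[states[i - 1], ])
  labels <- SLEEP_STATES[states]

  prof <- config$state_profile
  env <- function(col, per) rep(prof[[col]][states], each = per)

  delta <- band_limited_noise(n, fs, 0.5, 4)
  theta <- band_limited_noise(n, fs, 5, 9)
  broad <- one_over_f_noise(n, fs, 0.5, 100, exponent = 1)
  eeg <- env("delta_amp", spe) * delta + env("theta_amp", spe) * theta +
    env("broadband_amp", spe) * broad
  emg <- env("emg_rms", spe) * stats::rnorm(n)
  activity <- pmax(0, env("activity_level", spe_act) +
                     stats::rnorm(n_act, sd = config$activity_noise_sd))

  # spike trains: clusters of biphasic transients added onto the EEG
  wf <- spike_waveform(fs)
  peak_off <- round(length(wf) / 4)                # positive-peak sample
  k <- if (!is.null(config$n_spike_trains)) as.integer(config$n_spike_trains)
       else stats::rpois(1, config$spike_train_rate_per_hour *
                           config$duration_s / 3600)
  trains <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                       n_spikes = integer(0))
  if (k > 0 && config$spike_amplitude_uV > 0) {
    r <- config$spikes_per_train_range
    n_sp <- sample.int(r[2] - r[1] + 1L, k, replace = TRUE) + r[1] - 1L
    max_len <- (max(n_sp) - 1) * config$intra_train_gap_s + 0.1
    onsets <- place_trains(k, config$duration_s, max_len, min_sep = 5)
    for (j in seq_len(k)) {
      sp_times <- onsets[j] + (seq_len(n_sp[j]) - 1) * config$intra_train_gap_s
      for (st in sp_times) {
        i0 <- round(st * fs) - peak_off + 1
        idx <- i0:(i0 + length(wf) - 1)
        ok <- idx >= 1 & idx <= n
        eeg[idx[ok]] <- eeg[idx[ok]] + config$spike_amplitude_uV * wf[ok]
      }
      trains[j, ] <- list(sp_times[1], sp_times[n_sp[j]], n_sp[j])
    }
  }

  rec <- signal_recording(
    eeg = eeg, emg = emg, activity = activity,
    eeg_rate_hz = fs, activity_rate_hz = config$activity_rate_hz,
    duration_s = config$duration_s, subject_id = subject_id,
    group_label = group_label, activity_missing = FALSE
  )
  truth <- list(
    hypnogram = hypnogram(labels, config$epoch_len_s),
    spike_trains = trains
  )
  list(recording = rec, truth = truth)
}
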