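# Four-state vigilance scoring from per-epoch EEG band power, EMG tone and
# locomotor activity. Rule order: high EMG + movement -> active wake; high
# EMG alone -> wake; low EMG with theta-dominant EEG -> paradoxical sleep;
# otherwise slow-wave sleep.

#' Per-epoch features for sleep scoring
#'
#' For each consecutive epoch: delta and theta absolute band power of the
#' epoch's EEG (Welch, `window_len_s` segments), their ratio, the epoch EMG
#' RMS and the mean activity.
#'
#' @param recording a [signal_recording()].
#' @param epoch_len_s epoch length (s); must be at least one Welch window.
#' @param window_len_s Welch segment length used within each epoch (s).
#' @return data.frame with one row per complete epoch: `epoch`, `start_s`,
#'   `delta_power`, `theta_power`, `theta_delta_ratio` (NA when delta power
#'   is 0), `emg_rms`, `mean_activity`.
#' @export
epoch_features <- function(recording, epoch_len_s = 10, window_len_s = 2) {
  stopifnot(inherits(recording, "signal_recording"))
  if (epoch_len_s < window_len_s)
    stop("epoch_len_s must be at least one Welch window (", window_len_s,
         " s)")
  fs <- recording$eeg_rate_hz
  fa <- recording$activity_rate_hz
  n_epochs <- floor(recording$duration_s / epoch_len_s)
  spe <- round(epoch_len_s * fs)
  spa <- round(epoch_len_s * fa)
  bands <- data.frame(name = c("delta", "theta"), lo_hz = c(0.5, 5),
                      hi_hz = c(4, 9))
  rows <- lapply(seq_len(n_epochs), function(i) {
    eeg <- recording$eeg[((i - 1) * spe + 1):(i * spe)]
    emg <- recording$emg[((i - 1) * spe + 1):(i * spe)]
    act <- recording$activity[((i - 1) * spa + 1):(i * spa)]
    sp <- welch_psd(eeg, fs, window_len_s, overlap_frac = 0.5,
                    artifact_rms_factor = Inf)
    bp <- band_power(sp, bands)
    d <- bp$power_uV2[1]; th <- bp$power_uV2[2]
    data.frame(
      epoch = i, start_s = (i - 1) * epoch_len_s,
      delta_power = d, theta_power = th,
      theta_delta_ratio = if (d > 0) th / d else NA_real_,
      emg_rms = sqrt(mean(emg^2)), mean_activity = mean(act)
    )
  })
  do.call(rbind, rows)
}

# Bimodality-aware threshold between the "low" and "high" clusters of a
# feature: 2-means on the log scale with deterministic (min/max) starts,
# threshold at the midpoint of the cluster centres back on the raw scale.
bimodal_threshold <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (length(unique(x)) < 2) return(Inf)
  lx <- log(x)
  km <- stats::kmeans(lx, centers = matrix(range(lx), ncol = 1))
  exp(mean(km$centers))
}

#' Score epochs into the four vigilance states
#'
#' Decision rules, applied in order per epoch:
#' 1. `emg_rms > emg_threshold` and `mean_activity > activity_threshold`
#'    -> ACTIVE_WAKE;
#' 2. `emg_rms > emg_threshold` -> WAKE;
#' 3. `theta_delta_ratio > ratio_threshold` (with low EMG) -> PARADOXICAL;
#' 4. otherwise -> SWS.
#'
#' Thresholds are per-recording. The default EMG threshold separates the
#' low/high EMG clusters (2-means midpoint, scale-invariant); pass
#' `emg_threshold = "p60"` (or any "p<q>") for a fixed-percentile rule, or a
#' number for an absolute cutoff. The activity threshold defaults to the
#' recording's noise floor (median + 10 x MAD of epoch mean activity).
#' Epochs with missing features are labelled WAKE and counted in the
#' `n_unscorable` attribute.
#'
#' @param features data.frame from [epoch_features()].
#' @param epoch_len_s epoch length carried into the hypnogram (s).
#' @param emg_threshold "auto", "p<q>" or numeric (uV RMS).
#' @param activity_threshold "auto" or numeric (a.u.).
#' @param ratio_threshold theta/delta ratio above which a low-EMG epoch is
#'   paradoxical sleep.
#' @return A [hypnogram()] with the feature table attached; attributes
#'   `thresholds` and `n_unscorable`.
#' @export
score_epochs <- function(features, epoch_len_s = 10,
                         emg_threshold = "auto",
                         activity_threshold = "auto",
                         ratio_threshold = 1.5) {
  need <- c("delta_power", "theta_power", "theta_delta_ratio", "emg_rms",
            "mean_activity")
  stopifnot(all(need %in% names(features)))
  emg_thr <- if (is.numeric(emg_threshold)) emg_threshold
    else if (identical(emg_threshold, "auto")) bimodal_threshold(features$emg_rms)
    else if (grepl("^p[0-9.]+$", emg_threshold))
      stats::quantile(features$emg_rms,
                      as.numeric(sub("^p", "", emg_threshold)) / 100,
                      names = FALSE)
    else stop("emg_threshold must be 'auto', 'p<q>' or numeric")
  act <- features$mean_activity
  act_thr <- if (is.numeric(activity_threshold)) activity_threshold
    else stats::median(act) + 10 * stats::mad(act)
  unscorable <- !stats::complete.cases(features[, c("emg_rms",
                                                    "mean_activity")])
  ratio <- features$theta_delta_ratio
  ratio[is.na(ratio)] <- 0
  labels <- ifelse(
    features$emg_rms > emg_thr & features$mean_activity > act_thr,
    "ACTIVE_WAKE",
    ifelse(features$emg_rms > emg_thr, "WAKE",
           ifelse(ratio > ratio_threshold, "PARADOXICAL", "SWS"))
  )
  labels[unscorable] <- "WAKE"
  hyp <- hypnogram(labels, epoch_len_s, features = features)
  attr(hyp, "thresholds") <- list(emg = emg_thr, activity = act_thr,
                                  ratio = ratio_threshold)
  attr(hyp, "n_unscorable") <- sum(unscorable)
  hyp
}

#' Optional majority-vote smoothing of a hypnogram
#'
#' 3-epoch sliding majority; ties keep the centre label. Off by default in
#' the pipeline so state percentages stay unbiased.
#'
#' @param hyp a [hypnogram()].
#' @param width odd window width in epochs.
#' @return A smoothed [hypnogram()].
#' @export
smooth_hypnogram <- function(hyp, width = 3) {
  stopifnot(inherits(hyp, "hypnogram"), width %% 2 == 1)
  lab <- hyp$labels
  n <- length(lab)
  if (n < width) return(hyp)
  half <- (width - 1) / 2
  out <- lab
  for (i in (half + 1):(n - half)) {
    win <- lab[(i - half):(i + half)]
    tab <- table(win)
    if (max(tab) > half) out[i] <- names(tab)[which.max(tab)]
  }
  hypnogram(out, hyp$epoch_len_s, hyp$features)
}

#' Percent time per vigilance state
#'
#' @param hyp a [hypnogram()] with at least one epoch.
#' @return one-row data.frame: `percent_active_wake`, `percent_wake`,
#'   `percent_sws`, `percent_paradoxical`; the four sum to 100.
#' @export
state_percentages <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"), length(hyp$labels) >= 1)
  tab <- table(factor(hyp$labels, levels = SLEEP_STATES))
  pct <- 100 * as.numeric(tab) / length(hyp$labels)
  data.frame(
    percent_active_wake = pct[1], percent_wake = pct[2],
    percent_sws = pct[3], percent_paradoxical = pct[4]
  )
}
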