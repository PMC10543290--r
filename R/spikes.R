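# Epileptiform spike detection and spike-train grouping. Spikes are local
# extrema of the 1-70 Hz band-passed EEG exceeding a robust
# (median-absolute-deviation based) amplitude threshold; trains are
# single-linkage clusters of spikes in time.

#' Detect high-amplitude epileptiform spikes in the EEG
#'
#' The EEG is band-passed 1-70 Hz (4th-order Butterworth, zero-phase), a
#' robust baseline scale is taken as 1.4826 x the median absolute deviation,
#' and local extrema whose absolute amplitude exceeds
#' `threshold_sd x baseline` become spike events. Events closer than
#' `refractory_s` to a larger event are suppressed (keep-largest).
#'
#' @param recording a [signal_recording()].
#' @param threshold_sd amplitude threshold in baseline-scale units.
#' @param refractory_s minimum spacing between retained events (s).
#' @return data.frame with columns `time_s`, `amplitude_uV` (signed peak),
#'   sorted by time. A flat signal yields zero rows with a warning.
#' @export
detect_spikes <- function(recording, threshold_sd = 5, refractory_s = 0.05) {
  stopifnot(inherits(recording, "signal_recording"))
  if (threshold_sd <= 0) stop("threshold_sd must be > 0")
  fs <- recording$eeg_rate_hz
  bf <- signal::butter(4, c(1, min(70, 0.999 * fs / 2)) / (fs / 2), "pass")
  x <- signal::filtfilt(bf, recording$eeg)
  base <- robust_scale(x)
  empty <- data.frame(time_s = numeric(0), amplitude_uV = numeric(0))
  if (base == 0) {
    warning("flat (zero-variance) EEG; no spikes detected")
    return(empty)
  }
  thr <- threshold_sd * base
  a <- abs(x)
  n <- length(x)
  # strict local maxima of |x| above threshold
  cand <- which(a > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[a[cand] >= a[cand - 1] & a[cand] > a[cand + 1]]
  if (!length(cand)) return(empty)
  # keep-largest suppression within the refractory window
  ord <- cand[order(a[cand], decreasing = TRUE)]
  keep <- logical(0)
  kept <- numeric(0)
  ref_n <- refractory_s * fs
  for (i in ord) {
    if (!length(kept) || min(abs(kept - i)) > ref_n) kept <- c(kept, i)
  }
  kept <- sort(kept)
  data.frame(time_s = (kept - 1) / fs, amplitude_uV = x[kept])
}

#' Group spikes into spike trains
#'
#' Single-linkage clustering in time: consecutive spikes separated by at most
#' `max_gap_s` belong to one train; clusters with fewer than `min_spikes`
#' members are discarded. Train onset/offset are the first/last member spike
#' times.
#'
#' @param spikes data.frame from [detect_spikes()] (time-sorted).
#' @param max_gap_s maximum within-train gap between consecutive spikes (s).
#' @param min_spikes minimum spikes per retained train.
#' @return data.frame with columns `onset_s`, `offset_s`, `n_spikes`,
#'   `duration_s`, time-ordered and pairwise disjoint.
#' @export
group_spike_trains <- function(spikes, max_gap_s = 2, min_spikes = 3) {
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      n_spikes = integer(0), duration_s = numeric(0))
  if (!nrow(spikes)) return(empty)
  t <- spikes$time_s
  if (is.unsorted(t)) stop("spikes must be time-sorted")
  cl <- cumsum(c(1, diff(t) > max_gap_s))
  res <- do.call(rbind, lapply(split(t, cl), function(tt) {
    data.frame(onset_s = tt[1], offset_s = tt[length(tt)],
               n_spikes = length(tt),
               duration_s = tt[length(tt)] - tt[1])
  }))
  res <- res[res$n_spikes >= min_spikes, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Summarize spike trains over a recording
#'
#' @param trains data.frame from [group_spike_trains()].
#' @param recording_duration_s recording length (s).
#' @return one-row data.frame: `train_count`, `trains_per_hour`,
#'   `mean_duration_s` (NA when no trains), `total_spikes`.
#' @export
spike_train_summary <- function(trains, recording_duration_s) {
  stopifnot(recording_duration_s > 0)
  data.frame(
    train_count = nrow(trains),
    trains_per_hour = nrow(trains) / (recording_duration_s / 3600),
    mean_duration_s = if (nrow(trains)) mean(trains$duration_s) else NA_real_,
    total_spikes = if (nrow(trains)) sum(trains$n_spikes) else 0L
  )
}
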