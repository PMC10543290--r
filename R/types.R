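#' Vigilance state labels
#'
#' The four states scored by the pipeline: active wake (awake and moving),
#' wake (awake but still), slow-wave sleep (delta-dominant, low muscle tone)
#' and paradoxical sleep (theta-dominant, muscle atonia).
#'
#' @export
SLEEP_STATES <- c("ACTIVE_WAKE", "WAKE", "SWS", "PARADOXICAL")

#' Construct a multi-channel biopotential recording
#'
#' Container for one subject's telemetry record: EEG and EMG voltage series
#' (microvolts) sharing a sampling rate, plus a lower-rate locomotor activity
#' trace in arbitrary units.
#'
#' @param eeg numeric vector, EEG in microvolts.
#' @param emg numeric vector, EMG in microvolts; same sampling rate as EEG.
#' @param activity numeric vector, activity counts (arbitrary units).
#' @param eeg_rate_hz sampling rate of the biopotential channels (Hz).
#' @param activity_rate_hz sampling rate of the activity channel (Hz).
#' @param duration_s recording length in seconds.
#' @param subject_id subject identifier.
#' @param group_label group label, e.g. "WT" or "HET".
#' @param activity_missing logical; TRUE when the activity channel was absent
#'   from the source file and has been zero-filled.
#' @return An object of class `signal_recording`.
#' @export
signal_recording <- function(eeg, emg, activity = NULL,
                             eeg_rate_hz = 500, activity_rate_hz = 200,
                             duration_s = length(eeg) / eeg_rate_hz,
                             subject_id = "subject", group_label = "WT",
                             activity_missing = is.null(activity)) {
  if (eeg_rate_hz <= 0 || activity_rate_hz <= 0)
    stop("sampling rates must be strictly positive")
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (is.null(activity)) activity <- numeric(round(duration_s * activity_rate_hz))
  n_bio <- round(duration_s * eeg_rate_hz)
  n_act <- round(duration_s * activity_rate_hz)
  if (abs(length(eeg) - n_bio) > 1 || abs(length(emg) - n_bio) > 1)
    stop("eeg/emg length inconsistent with duration_s * eeg_rate_hz")
  if (abs(length(activity) - n_act) > 1)
    stop("activity length inconsistent with duration_s * activity_rate_hz")
  if (length(eeg) != length(emg))
    stop("eeg and emg must share a sampling rate and length")
  structure(list(
    eeg = as.numeric(eeg), emg = as.numeric(emg),
    activity = as.numeric(activity),
    eeg_rate_hz = eeg_rate_hz, activity_rate_hz = activity_rate_hz,
    duration_s = duration_s, subject_id = subject_id,
    group_label = group_label, activity_missing = activity_missing
  ), class = "signal_recording")
}

#' @export
print.signal_recording <- function(x, ...) {
  cat(sprintf(
    "<signal_recording> %s [%s]: %.1f s, EEG/EMG @ %g Hz, activity @ %g Hz%s\n",
    x$subject_id, x$group_label, x$duration_s, x$eeg_rate_hz,
    x$activity_rate_hz, if (x$activity_missing) " (activity zero-filled)" else ""
  ))
  invisible(x)
}

#' Construct an MEA spike raster
#'
#' Event-list representation of a high-density microelectrode array recording:
#' one row per detected spike, with 0-based electrode ids on a rows x cols grid.
#'
#' @param events data.frame with columns `electrode_id` (integer, 0-based) and
#'   `spike_time_s` (seconds from recording start).
#' @param n_electrodes electrodes on the array (full chip: 26400).
#' @param duration_s recording length (s).
#' @param array_shape integer pair (rows, cols); rows*cols must equal
#'   `n_electrodes`.
#' @param chip_id chip identifier.
#' @param group_label group label, e.g. "WT" or "HET".
#' @param div day in vitro of the recording (NA if not applicable).
#' @return An object of class `spike_raster`, events sorted by
#'   (spike_time_s, electrode_id).
#' @export
spike_raster <- function(events, n_electrodes = 26400L, duration_s,
                         array_shape = NULL, chip_id = "chip",
                         group_label = "WT", div = NA_integer_) {
  stopifnot(is.data.frame(events))
  if (!all(c("electrode_id", "spike_time_s") %in% names(events)))
    stop("events needs columns electrode_id, spike_time_s")
  if (is.null(array_shape)) {
    array_shape <- c(120L, ceiling(n_electrodes / 120))
    if (prod(array_shape) != n_electrodes) array_shape <- c(1L, n_electrodes)
  }
  if (prod(array_shape) != n_electrodes)
    stop("array_shape rows*cols must equal n_electrodes")
  if (nrow(events)) {
    bad <- which(events$spike_time_s < 0 | events$spike_time_s >= duration_s)
    if (length(bad))
      stop(sprintf("event time out of [0, duration_s) at row %d", bad[1]))
    if (any(events$electrode_id < 0 | events$electrode_id >= n_electrodes))
      stop("electrode_id out of range")
    events <- events[order(events$spike_time_s, events$electrode_id), ,
                     drop = FALSE]
    rownames(events) <- NULL
  }
  structure(list(
    events = events, n_electrodes = as.integer(n_electrodes),
    duration_s = duration_s, array_shape = as.integer(array_shape),
    chip_id = chip_id, group_label = group_label, div = div
  ), class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf(
    "<spike_raster> %s [%s]: %d events / %d electrodes, %.0f s%s\n",
    x$chip_id, x$group_label, nrow(x$events), x$n_electrodes, x$duration_s,
    if (!is.na(x$div)) sprintf(", DIV%d", x$div) else ""
  ))
  invisible(x)
}

#' Construct a hypnogram
#'
#' @param labels character vector of per-epoch state labels (see
#'   [SLEEP_STATES]).
#' @param epoch_len_s epoch length in seconds.
#' @param features optional per-epoch feature table (one row per epoch).
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_len_s, features = NULL) {
  labels <- as.character(labels)
  if (!all(labels %in% SLEEP_STATES))
    stop("labels must be one of ", paste(SLEEP_STATES, collapse = ", "))
  if (epoch_len_s <= 0) stop("epoch_len_s must be > 0")
  if (!is.null(features) && nrow(features) != length(labels))
    stop("features must have one row per epoch")
  structure(list(labels = labels, epoch_len_s = epoch_len_s,
                 features = features), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = SLEEP_STATES))
  cat(sprintf("<hypnogram> %d epochs x %g s: %s\n", length(x$labels),
              x$epoch_len_s,
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}
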