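# Synthetic HD-MEA raster generator: homogeneous Poisson background firing on
# a subset of active electrodes, plus synchronized network bursts in which
# participating electrodes transiently multiply their rate.

#' Configuration for the synthetic MEA raster generator
#'
#' @param n_electrodes electrodes on the array (full chip 26400).
#' @param n_active_electrodes electrodes that fire at all.
#' @param duration_s recording length (activity scan 30 s, network assay
#'   300 s).
#' @param baseline_rate_hz per-electrode background Poisson rate (Hz).
#' @param burst_rate_per_min rate of network-burst onsets (per minute).
#' @param burst_duration_s duration of each burst (s).
#' @param within_burst_rate_multiplier rate multiplier for participating
#'   electrodes during a burst.
#' @param electrode_participation_prob probability an active electrode joins
#'   a given burst.
#' @param rng_seed integer seed; fixed seed gives identical rasters.
#' @return A list of class `mea_sim_config`.
#' @export
mea_sim_config <- function(n_electrodes = 26400L, n_active_electrodes = 1024L,
                           duration_s = 300, baseline_rate_hz = 1,
                           burst_rate_per_min = 4, burst_duration_s = 0.3,
                           within_burst_rate_multiplier = 20,
                           electrode_participation_prob = 0.6,
                           rng_seed = NULL) {
  if (electrode_participation_prob < 0 || electrode_participation_prob > 1)
    stop("electrode_participation_prob must be in [0, 1]")
  if (baseline_rate_hz < 0 || burst_rate_per_min < 0 ||
      within_burst_rate_multiplier < 0)
    stop("rates must be >= 0")
  if (n_active_electrodes > n_electrodes)
    stop("n_active_electrodes must be <= n_electrodes")
  if (burst_rate_per_min > 0 && burst_duration_s >= duration_s)
    stop("burst_duration_s must be shorter than the recording")
  structure(list(
    n_electrodes = as.integer(n_electrodes),
    n_active_electrodes = as.integer(n_active_electrodes),
    duration_s = duration_s, baseline_rate_hz = baseline_rate_hz,
    burst_rate_per_min = burst_rate_per_min,
    burst_duration_s = burst_duration_s,
    within_burst_rate_multiplier = within_burst_rate_multiplier,
    electrode_participation_prob = electrode_participation_prob,
    rng_seed = rng_seed
  ), class = "mea_sim_config")
}

#' Simulate an MEA spike raster with known burst ground truth
#'
#' Burst onsets follow a thinned Poisson process: successive onsets are drawn
#' with an exponential gap on top of a guard interval (burst duration plus
#' 0.1 s), so ground-truth burst windows never overlap.
#'
#' @param config an [mea_sim_config()].
#' @param chip_id,group_label,div metadata for the resulting raster.
#' @return A list with elements `raster` (a [spike_raster()]) and `truth`
#'   (list: `bursts` data.frame with onset_s/peak_s/offset_s/n_spikes,
#'   `active_electrodes` 0-based id vector).
#' @export
simulate_raster <- function(config, chip_id = "chip", group_label = "WT",
                            div = NA_integer_) {
  stopifnot(inherits(config, "mea_sim_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  dur <- config$duration_s
  active <- sort(sample.int(config$n_electrodes,
                            config$n_active_electrodes) - 1L)

  # background firing
  counts <- stats::rpois(length(active), config$baseline_rate_hz * dur)
  ev_id <- rep(active, counts)
  ev_t <- stats::runif(sum(counts), 0, dur)

  # non-overlapping burst windows
  bursts <- data.frame(onset_s = numeric(0), peak_s = numeric(0),
                       offset_s = numeric(0), n_spikes = integer(0))
  if (config$burst_rate_per_min > 0) {
    rate_s <- config$burst_rate_per_min / 60
    guard <- config$burst_duration_s + 0.1
    t <- stats::rexp(1, rate_s)
    while (t + config$burst_duration_s < dur) {
      onset <- t; offset <- t + config$burst_duration_s
      part <- active[stats::runif(length(active)) <
                       config$electrode_participation_prob]
      extra_rate <- config$baseline_rate_hz *
        (config$within_burst_rate_multiplier - 1)
      nsp <- stats::rpois(length(part), extra_rate * config$burst_duration_s)
      ev_id <- c(ev_id, rep(part, nsp))
      ev_t <- c(ev_t, stats::runif(sum(nsp), onset, offset))
      bursts[nrow(bursts) + 1, ] <-
        list(onset, (onset + offset) / 2, offset, sum(nsp))
      t <- offset + 0.1 + stats::rexp(1, rate_s)
    }
  }

  raster <- spike_raster(
    events = data.frame(electrode_id = ev_id, spike_time_s = ev_t),
    n_electrodes = config$n_electrodes, duration_s = dur,
    chip_id = chip_id, group_label = group_label, div = div
  )
  list(raster = raster, truth = list(bursts = bursts,
                                     active_electrodes = active))
}
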