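# HD-MEA network analysis: per-electrode activity scan, selection of the
# highest-firing electrodes, Gaussian-smoothed population rate, network-burst
# detection on the smoothed trace, and per-chip burst metrics across days in
# vitro.

#' Per-electrode firing rates from an activity scan
#'
#' @param raster a [spike_raster()].
#' @param scan_duration_s window [0, scan_duration_s) over which rates are
#'   computed (the activity-scan convention is 30 s per electrode).
#' @return data.frame with one row per electrode on the array:
#'   `electrode_id`, `rate_hz`.
#' @export
activity_scan <- function(raster, scan_duration_s = 30) {
  stopifnot(inherits(raster, "spike_raster"))
  if (scan_duration_s > raster$duration_s + 1e-9)
    stop("scan_duration_s exceeds raster duration")
  ev <- raster$events[raster$events$spike_time_s < scan_duration_s, ,
                      drop = FALSE]
  counts <- tabulate(ev$electrode_id + 1L, nbins = raster$n_electrodes)
  data.frame(electrode_id = seq_len(raster$n_electrodes) - 1L,
             rate_hz = counts / scan_duration_s)
}

#' Select the highest-firing electrodes
#'
#' Ties are broken by ascending electrode id. Electrodes with zero rate are
#' never selected; if fewer than `n` electrodes fired, all firing electrodes
#' are returned and the shortfall reported via a warning.
#'
#' @param scan data.frame from [activity_scan()].
#' @param n electrodes to select (network-assay convention: 1024).
#' @return integer vector of 0-based electrode ids, ascending.
#' @export
select_top_electrodes <- function(scan, n = 1024L) {
  if (n <= 0) stop("n must be > 0")
  pos <- scan[scan$rate_hz > 0, , drop = FALSE]
  pos <- pos[order(-pos$rate_hz, pos$electrode_id), , drop = FALSE]
  if (nrow(pos) < n)
    warning(sprintf("only %d electrodes have nonzero rate (requested %d)",
                    nrow(pos), n))
  sort(pos$electrode_id[seq_len(min(n, nrow(pos)))])
}

#' Gaussian-smoothed population firing rate
#'
#' Spike times of the selected electrodes are pooled, binned at `dt`, and
#' convolved with a unit-area Gaussian kernel (truncated at +/- 4 sigma), so
#' the trace integrates to the pooled spike count (up to truncated kernel
#' mass and edge effects).
#'
#' @param raster a [spike_raster()].
#' @param electrodes 0-based ids to pool; NULL pools every electrode.
#' @param kernel_sigma_s Gaussian kernel width (s).
#' @param dt time step of the output grid (s); must be <= sigma/2.
#' @return An object of class `network_trace`: list with `time_s`, `rate`
#'   (spikes/s), `dt`, `kernel_sigma_s`, `n_electrodes_pooled`,
#'   `n_spikes_pooled`.
#' @export
network_trace <- function(raster, electrodes = NULL, kernel_sigma_s = 0.05,
                          dt = 0.01) {
  stopifnot(inherits(raster, "spike_raster"))
  if (kernel_sigma_s <= 0) stop("kernel_sigma_s must be > 0")
  if (dt <= 0 || dt > kernel_sigma_s / 2)
    stop("dt must be positive and at most kernel_sigma_s / 2")
  ev <- raster$events
  if (!is.null(electrodes)) {
    ev <- ev[ev$electrode_id %in% electrodes, , drop = FALSE]
    if (!nrow(ev) && !length(electrodes))
      warning("empty electrode set; trace is all zero")
  }
  nb <- ceiling(raster$duration_s / dt)
  grid <- (seq_len(nb) - 0.5) * dt
  counts <- tabulate(pmin(nb, floor(ev$spike_time_s / dt) + 1L), nbins = nb)
  half <- ceiling(4 * kernel_sigma_s / dt)
  kt <- (-half:half) * dt
  kern <- stats::dnorm(kt, sd = kernel_sigma_s)
  kern <- kern / (sum(kern) * dt)                     # unit area on the grid
  rate <- stats::convolve(counts, rev(kern), type = "open")
  rate <- pmax(0, rate[(half + 1):(half + nb)])       # centre of full conv
  structure(list(
    time_s = grid, rate = as.numeric(rate),
    dt = dt, kernel_sigma_s = kernel_sigma_s,
    n_electrodes_pooled = if (is.null(electrodes))
      raster$n_electrodes else length(electrodes),
    n_spikes_pooled = nrow(ev)
  ), class = "network_trace")
}

#' @export
print.network_trace <- function(x, ...) {
  cat(sprintf(
    "<network_trace> %d bins @ %g s, sigma = %g s, %d spikes from %d electrodes\n",
    length(x$time_s), x$dt, x$kernel_sigma_s, x$n_spikes_pooled,
    x$n_electrodes_pooled
  ))
  invisible(x)
}

#' Detect network bursts on a smoothed population-rate trace
#'
#' Threshold = baseline + k x spread, where baseline is the trace median and
#' spread its scaled median absolute deviation, with a floor of 2 x baseline.
#' Contiguous supra-threshold regions are candidate bursts; each candidate's
#' peak is its maximum, onset/offset are extended outward to where the trace
#' falls below baseline + 10% of (peak - baseline), and candidates whose
#' peaks are closer than `merge_gap_s` merge. Spike counts are pooled events
#' of the selected electrodes within [onset, offset].
#'
#' @param trace a `network_trace` from [network_trace()].
#' @param raster the [spike_raster()] the trace came from.
#' @param electrodes 0-based ids pooled into the trace (NULL = all).
#' @param k threshold multiplier on the robust spread.
#' @param merge_gap_s peaks closer than this merge into one burst (s).
#' @return data.frame with columns `onset_s`, `peak_time_s`, `offset_s`,
#'   `duration_s`, `n_spikes`, `peak_rate`, time-ordered.
#' @export
detect_bursts <- function(trace, raster, electrodes = NULL, k = 5,
                          merge_gap_s = 0.2) {
  stopifnot(inherits(trace, "network_trace"))
  empty <- data.frame(onset_s = numeric(0), peak_time_s = numeric(0),
                      offset_s = numeric(0), duration_s = numeric(0),
                      n_spikes = integer(0), peak_rate = numeric(0))
  r <- trace$rate
  if (all(r == 0)) return(empty)
  baseline <- stats::median(r)
  spread <- stats::mad(r, constant = 1.4826)
  thr <- max(baseline + k * spread, 2 * baseline)
  above <- r > thr
  if (!any(above)) return(empty)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  si <- starts[runs$values]; ei <- ends[runs$values]

  # extend each candidate to the 10%-of-peak-height crossing
  n <- length(r)
  cand <- lapply(seq_along(si), function(j) {
    pk <- si[j] - 1 + which.max(r[si[j]:ei[j]])
    lvl <- baseline + 0.1 * (r[pk] - baseline)
    a <- si[j]; while (a > 1 && r[a - 1] >= lvl) a <- a - 1
    b <- ei[j]; while (b < n && r[b + 1] >= lvl) b <- b + 1
    c(a, pk, b)
  })
  m <- do.call(rbind, cand)

  # merge candidates with nearby peaks (or overlapping extents)
  merged <- list()
  cur <- m[1, ]
  if (nrow(m) > 1) for (j in 2:nrow(m)) {
    close_peaks <- (m[j, 2] - cur[2]) * trace$dt < merge_gap_s
    overlap <- m[j, 1] <= cur[3]
    if (close_peaks || overlap) {
      if (r[m[j, 2]] > r[cur[2]]) cur[2] <- m[j, 2]
      cur[3] <- max(cur[3], m[j, 3])
      cur[1] <- min(cur[1], m[j, 1])
    } else {
      merged[[length(merged) + 1]] <- cur
      cur <- m[j, ]
    }
  }
  merged[[length(merged) + 1]] <- cur
  m <- do.call(rbind, merged)

  ev <- raster$events
  if (!is.null(electrodes))
    ev <- ev[ev$electrode_id %in% electrodes, , drop = FALSE]
  onset <- trace$time_s[m[, 1]] - trace$dt / 2
  offset <- trace$time_s[m[, 3]] + trace$dt / 2
  data.frame(
    onset_s = onset,
    peak_time_s = trace$time_s[m[, 2]],
    offset_s = offset,
    duration_s = offset - onset,
    n_spikes = vapply(seq_len(nrow(m)), function(j)
      sum(ev$spike_time_s >= onset[j] & ev$spike_time_s <= offset[j]),
      integer(1)),
    peak_rate = r[m[, 2]]
  )
}

#' Per-chip burst metrics
#'
#' Inter-burst interval is peak-to-peak: the mean gap between successive
#' burst peaks (NA with fewer than two bursts).
#'
#' @param bursts data.frame from [detect_bursts()], time-ordered.
#' @param div day in vitro of the recording.
#' @param chip_id chip identifier.
#' @param group_label group label.
#' @return one-row data.frame: `chip_id`, `group_label`, `div`, `n_bursts`,
#'   `spikes_per_burst`, `inter_burst_interval_s`, `burst_duration_s`.
#' @export
burst_metrics <- function(bursts, div = NA_integer_, chip_id = "chip",
                          group_label = "WT") {
  nb <- nrow(bursts)
  data.frame(
    chip_id = chip_id, group_label = group_label, div = div,
    n_bursts = nb,
    spikes_per_burst = if (nb) mean(bursts$n_spikes) else NA_real_,
    inter_burst_interval_s = if (nb >= 2) mean(diff(bursts$peak_time_s))
      else NA_real_,
    burst_duration_s = if (nb) mean(bursts$duration_s) else NA_real_
  )
}

#' Longitudinal (group x DIV) summary of burst metrics
#'
#' @param metrics data.frame of stacked [burst_metrics()] rows.
#' @return data.frame with one row per (group_label, div, metric):
#'   `mean`, `sem` (NA for a single chip), `n_chips`.
#' @export
div_trajectory <- function(metrics) {
  stopifnot(all(c("group_label", "div") %in% names(metrics)))
  cols <- c("n_bursts", "spikes_per_burst", "inter_burst_interval_s",
            "burst_duration_s")
  cols <- intersect(cols, names(metrics))
  out <- do.call(rbind, lapply(split(metrics,
                                     list(metrics$group_label, metrics$div),
                                     drop = TRUE), function(g) {
    do.call(rbind, lapply(cols, function(cl) {
      v <- g[[cl]][!is.na(g[[cl]])]
      data.frame(
        group_label = g$group_label[1], div = g$div[1], metric = cl,
        mean = if (length(v)) mean(v) else NA_real_,
        sem = if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_,
        n_chips = length(v)
      )
    }))
  }))
  rownames(out) <- NULL
  out[order(out$div, out$group_label, out$metric), ]
}
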