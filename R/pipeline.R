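# End-to-end orchestration over simulated or ingested cohorts. Each run
# returns (and optionally writes) per-subject metrics plus the group
# comparisons, with the resolved configuration and seeds in a manifest so
# any output can be reproduced.

#' Run the EEG phenotyping pipeline on a cohort
#'
#' For each subject: Welch PSD, delta/theta/alpha/beta/gamma band powers,
#' spike-train detection and summary, sleep scoring and state percentages.
#' With two groups present, group comparisons (pooled t tests after the 2-SD
#' inclusion filter) are run for each metric.
#'
#' @param subjects either a list of [signal_recording()]s, or a data.frame
#'   with columns `subject_id`, `group_label`, `seed` describing simulated
#'   subjects (simulated from the genotype presets).
#' @param epoch_len_s scoring epoch length (s).
#' @param window_len_s Welch segment length (s).
#' @param threshold_sd,max_gap_s,min_spikes spike-detection parameters
#'   (see [detect_spikes()], [group_spike_trains()]).
#' @param out_dir optional directory; when given, metric CSVs and a JSON
#'   manifest are written there.
#' @return list: `subject_metrics` (one row per subject), `band_powers`
#'   (long table), `comparisons` (or NULL with a notice when fewer than two
#'   groups), `manifest`.
#' @export
run_eeg_pipeline <- function(subjects, epoch_len_s = 10, window_len_s = 2,
                             threshold_sd = 5, max_gap_s = 2, min_spikes = 3,
                             out_dir = NULL) {
  if (is.data.frame(subjects)) {
    spec <- subjects
    recs <- lapply(seq_len(nrow(spec)), function(i) {
      cfg <- genotype_preset(spec$group_label[i])$eeg
      cfg$rng_seed <- spec$seed[i]
      simulate_eeg(cfg, subject_id = spec$subject_id[i],
                   group_label = spec$group_label[i])$recording
    })
  } else {
    recs <- subjects
  }
  stopifnot(length(recs) >= 1,
            all(vapply(recs, inherits, logical(1), "signal_recording")))

  bp_rows <- list(); subj_rows <- list()
  for (rec in recs) {
    sp <- compute_psd(rec, window_len_s = window_len_s)
    bp <- band_power(sp, subject_id = rec$subject_id)
    bp$group_label <- rec$group_label
    bp_rows[[rec$subject_id]] <- bp
    spikes <- detect_spikes(rec, threshold_sd = threshold_sd)
    trains <- group_spike_trains(spikes, max_gap_s = max_gap_s,
                                 min_spikes = min_spikes)
    ts <- spike_train_summary(trains, rec$duration_s)
    feats <- epoch_features(rec, epoch_len_s, window_len_s)
    hyp <- score_epochs(feats, epoch_len_s)
    pct <- state_percentages(hyp)
    subj_rows[[rec$subject_id]] <- cbind(
      data.frame(subject_id = rec$subject_id, group_label = rec$group_label),
      data.frame(delta_power = bp$power_uV2[bp$band == "delta"],
                 theta_power = bp$power_uV2[bp$band == "theta"]),
      ts, pct)
  }
  subject_metrics <- do.call(rbind, c(subj_rows, list(make.row.names = FALSE)))
  band_powers <- do.call(rbind, c(bp_rows, list(make.row.names = FALSE)))

  groups <- unique(subject_metrics$group_label)
  metrics <- c("delta_power", "theta_power", "train_count",
               "mean_duration_s", "percent_active_wake", "percent_wake",
               "percent_sws", "percent_paradoxical")
  if (length(groups) == 2) {
    comparisons <- do.call(rbind, lapply(metrics, function(m) {
      flt <- suppressWarnings(
        filter_2sd(subject_metrics[[m]], subject_metrics$group_label))
      v <- flt$retained
      a <- v$value[v$group == groups[1]]; b <- v$value[v$group == groups[2]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      res <- group_t_test(a, b)
      cbind(data.frame(metric = m, group_a = groups[1], group_b = groups[2],
                       n_excluded = nrow(flt$excluded)), res)
    }))
  } else {
    comparisons <- NULL
    message("fewer than two groups; comparisons skipped")
  }

  manifest <- list(
    stage = "eeg", n_subjects = length(recs),
    subjects = data.frame(
      subject_id = vapply(recs, `[[`, character(1), "subject_id"),
      group_label = vapply(recs, `[[`, character(1), "group_label")),
    parameters = list(epoch_len_s = epoch_len_s,
                      window_len_s = window_len_s,
                      threshold_sd = threshold_sd, max_gap_s = max_gap_s,
                      min_spikes = min_spikes),
    seeds = if (is.data.frame(subjects)) subjects$seed else NULL,
    package_version = as.character(utils::packageVersion("ephyspheno"))
  )
  out <- list(subject_metrics = subject_metrics, band_powers = band_powers,
              comparisons = comparisons, manifest = manifest)
  if (!is.null(out_dir)) write_report_bundle(out, out_dir)
  out
}

#' Run the MEA phenotyping pipeline on a cohort of chips
#'
#' Per chip: activity scan, top-electrode selection, Gaussian-smoothed
#' network trace, burst detection and burst metrics; across chips: the
#' (group x DIV) trajectory and, with two groups, a two-way ANOVA per burst
#' metric.
#'
#' @param chips either a list of [spike_raster()]s, or a data.frame with
#'   columns `chip_id`, `group_label`, `div`, `seed` describing simulated
#'   chips (simulated from the genotype presets at each DIV).
#' @param scan_duration_s activity-scan window (s).
#' @param n_top electrodes selected for the network analysis.
#' @param kernel_sigma_s,dt network-trace smoothing parameters.
#' @param k burst-threshold multiplier.
#' @param out_dir optional output directory, as in [run_eeg_pipeline()].
#' @return list: `chip_metrics`, `trajectory`, `anova` (or NULL), `manifest`.
#' @export
run_mea_pipeline <- function(chips, scan_duration_s = 30, n_top = 1024L,
                             kernel_sigma_s = 0.05, dt = 0.01, k = 5,
                             out_dir = NULL) {
  if (is.data.frame(chips)) {
    spec <- chips
    rasters <- lapply(seq_len(nrow(spec)), function(i) {
      cfg <- genotype_preset(spec$group_label[i], div = spec$div[i])$mea
      cfg$rng_seed <- spec$seed[i]
      simulate_raster(cfg, chip_id = spec$chip_id[i],
                      group_label = spec$group_label[i],
                      div = spec$div[i])$raster
    })
  } else {
    rasters <- chips
  }
  stopifnot(length(rasters) >= 1,
            all(vapply(rasters, inherits, logical(1), "spike_raster")))

  chip_metrics <- do.call(rbind, lapply(rasters, function(r) {
    scan <- activity_scan(r, min(scan_duration_s, r$duration_s))
    top <- suppressWarnings(select_top_electrodes(scan, n_top))
    tr <- network_trace(r, top, kernel_sigma_s, dt)
    bursts <- detect_bursts(tr, r, top, k = k)
    cbind(burst_metrics(bursts, div = r$div, chip_id = r$chip_id,
                        group_label = r$group_label),
          data.frame(n_electrodes_selected = length(top),
                     pooled_spikes = tr$n_spikes_pooled))
  }))
  rownames(chip_metrics) <- NULL

  trajectory <- div_trajectory(chip_metrics)
  groups <- unique(chip_metrics$group_label)
  divs <- unique(chip_metrics$div[!is.na(chip_metrics$div)])
  if (length(groups) == 2 && length(divs) >= 2 && nrow(chip_metrics) > 4) {
    anova <- do.call(rbind, lapply(
      c("n_bursts", "spikes_per_burst", "inter_burst_interval_s",
        "burst_duration_s"),
      function(m) {
        tab <- data.frame(id = chip_metrics$chip_id,
                          value = chip_metrics[[m]],
                          group_label = chip_metrics$group_label,
                          div = chip_metrics$div)
        res <- tryCatch(two_way_anova(tab, "group_label", "div"),
                        error = function(e) NULL)
        if (is.null(res)) return(NULL)
        cbind(data.frame(metric = m), res)
      }))
  } else {
    anova <- NULL
    if (length(groups) < 2 || length(divs) < 2)
      message("need two groups and two DIVs for the genotype x DIV ANOVA; skipped")
  }

  manifest <- list(
    stage = "mea", n_chips = length(rasters),
    parameters = list(scan_duration_s = scan_duration_s, n_top = n_top,
                      kernel_sigma_s = kernel_sigma_s, dt = dt, k = k),
    seeds = if (is.data.frame(chips)) chips$seed else NULL,
    package_version = as.character(utils::packageVersion("ephyspheno"))
  )
  out <- list(chip_metrics = chip_metrics, trajectory = trajectory,
              anova = anova, manifest = manifest)
  if (!is.null(out_dir)) write_report_bundle(out, out_dir)
  out
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle)) {
    x <- bundle[[nm]]
    if (is.data.frame(x))
      write_metrics_csv(x, file.path(out_dir, paste0(nm, ".csv")))
  }
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
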