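#!/usr/bin/env Rscript
# Stage 6: genotype statistics over the stage 2-5 metric tables.
#
# Single-parameter genotype contrasts use the 2-SD inclusion filter followed
# by a pooled-variance two-tailed t test; the longitudinal burst metrics use
# a two-way (genotype x DIV) ANOVA with Sidak-adjusted per-DIV contrasts.

library(ephyspheno)

trains <- read.csv("results/spike_trains.csv")
states <- read.csv("results/state_percentages.csv")
eeg <- merge(trains, states, by = c("subject_id", "group_label"))
bands <- read.csv("results/band_powers.csv")
for (bd in c("delta", "theta")) {
  w <- bands[bands$band == bd, c("subject_id", "power_uV2")]
  names(w)[2] <- paste0(bd, "_power")
  eeg <- merge(eeg, w, by = "subject_id")
}

metrics <- c("delta_power", "theta_power", "train_count", "mean_duration_s",
             "percent_active_wake", "percent_wake", "percent_sws",
             "percent_paradoxical")
comparisons <- do.call(rbind, lapply(metrics, function(mt) {
  flt <- suppressWarnings(filter_2sd(eeg[[mt]], eeg$group_label))
  v <- flt$retained
  res <- group_t_test(v$value[v$group == "WT"], v$value[v$group == "HET"])
  cbind(data.frame(metric = mt, n_excluded = nrow(flt$excluded)), res)
}))
write_metrics_csv(comparisons, "results/comparisons_eeg.csv")
cat("genotype t tests (WT = a, HET = b):\n")
print(comparisons[, c("metric", "statistic", "df", "p_value", "direction")],
      row.names = FALSE, digits = 3)

bursts <- read.csv("results/burst_metrics.csv")
anova_rows <- do.call(rbind, lapply(
  c("n_bursts", "spikes_per_burst", "inter_burst_interval_s",
    "burst_duration_s"),
  function(mt) {
    tab <- data.frame(id = bursts$chip_id, value = bursts[[mt]],
                      group_label = bursts$group_label, div = bursts$div)
    cbind(data.frame(metric = mt), two_way_anova(tab, "group_label", "div"))
  }))
write_metrics_csv(anova_rows, "results/anova_mea.csv")
cat("\ntwo-way genotype x DIV ANOVA on burst metrics:\n")
print(anova_rows[, c("metric", "effect", "df1", "df2", "F", "p_value")],
      row.names = FALSE, digits = 3)

# per-DIV genotype contrasts on the inter-burst interval, Sidak-adjusted
divs <- sort(unique(bursts$div))
per_div <- do.call(rbind, lapply(divs, function(d) {
  b <- bursts[bursts$div == d, ]
  res <- group_t_test(
    b$inter_burst_interval_s[b$group_label == "WT"],
    b$inter_burst_interval_s[b$group_label == "HET"])
  cbind(data.frame(div = d), res)
}))
per_div$adjusted_p <- posthoc_adjust(per_div$p_value, "sidak")
write_metrics_csv(per_div, "results/posthoc_ibi.csv")
cat("\nper-DIV inter-burst-interval contrasts (Sidak-adjusted):\n")
print(per_div[, c("div", "statistic", "p_value", "adjusted_p", "direction")],
      row.names = FALSE, digits = 3)
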