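#!/usr/bin/env Rscript
# Stage 5: HD-MEA network bursts per chip across days in vitro.
#
# Per chip: 30 s activity scan over all 26,400 electrodes, selection of the
# 1024 highest-firing electrodes, Gaussian-smoothed (sigma = 50 ms)
# population rate over the 300 s network recording, burst detection and the
# burst metrics (count, spikes/burst, inter-burst interval, duration).

library(ephyspheno)

cohort <- read.csv("results/cohort_mea.csv")
out <- run_mea_pipeline(cohort, scan_duration_s = 30, n_top = 1024L,
                        kernel_sigma_s = 0.05, dt = 0.01)
write_metrics_csv(out$chip_metrics, "results/burst_metrics.csv")
write_metrics_csv(out$trajectory, "results/burst_trajectory.csv")

cat(sprintf("analyzed %d chip-recordings\n", nrow(out$chip_metrics)))
ibi <- out$trajectory[out$trajectory$metric == "inter_burst_interval_s", ]
for (d in sort(unique(ibi$div))) {
  r <- ibi[ibi$div == d, ]
  cat(sprintf("DIV%02d inter-burst interval: WT %5.1f s, HET %5.1f s\n", d,
              r$mean[r$group_label == "WT"], r$mean[r$group_label == "HET"]))
}
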