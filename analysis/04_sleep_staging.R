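#!/usr/bin/env Rscript
# Stage 4: four-state sleep scoring and state percentages per subject.
#
# 10 s epochs are scored from delta/theta band power, EMG RMS and activity;
# staging accuracy is reported against the generating hypnogram (available
# here because the cohort is synthetic).

library(ephyspheno)

cohort <- read.csv("results/cohort_eeg.csv")
rows <- lapply(seq_len(nrow(cohort)), function(i) {
  cfg <- genotype_preset(cohort$group_label[i])$eeg
  cfg$rng_seed <- cohort$seed[i]
  sim <- simulate_eeg(cfg, subject_id = cohort$subject_id[i],
                      group_label = cohort$group_label[i])
  hyp <- score_epochs(epoch_features(sim$recording, 10), 10)
  cbind(data.frame(subject_id = cohort$subject_id[i],
                   group_label = cohort$group_label[i],
                   agreement = mean(hyp$labels ==
                                      sim$truth$hypnogram$labels)),
        state_percentages(hyp))
})
states <- do.call(rbind, rows)
write_metrics_csv(states, "results/state_percentages.csv")

cat(sprintf("staging agreement vs ground truth: mean %.1f%%, min %.1f%%\n",
            100 * mean(states$agreement), 100 * min(states$agreement)))
for (cl in c("percent_active_wake", "percent_wake", "percent_sws",
             "percent_paradoxical")) {
  mu <- tapply(states[[cl]], states$group_label, mean)
  cat(sprintf("%-22s WT %5.1f%%  HET %5.1f%%\n", cl, mu["WT"], mu["HET"]))
}
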