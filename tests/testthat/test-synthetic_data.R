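test_that("spike injection honors the configured count, including zero", {
  cfg <- eeg_sim_config(duration_s = 120, spike_train_rate_per_hour = 0,
                        spike_amplitude_uV = 0, rng_seed = 1)
  sim <- simulate_eeg(cfg)
  expect_equal(nrow(sim$truth$spike_trains), 0)

  sim5 <- simulate_eeg(flat_eeg_config(600, n_trains = 5, seed = 2))
  expect_equal(nrow(sim5$truth$spike_trains), 5)
  expect_true(all(sim5$truth$spike_trains$onset_s >= 0))
  expect_true(all(sim5$truth$spike_trains$offset_s < 600))
  # non-overlapping, ordered train intervals
  expect_true(all(diff(sim5$truth$spike_trains$onset_s) > 0))
  expect_true(all(utils::head(sim5$truth$spike_trains$offset_s, -1) <
                    utils::tail(sim5$truth$spike_trains$onset_s, -1)))
})

test_that("a transition matrix pinned to SWS yields an all-SWS hypnogram", {
  P <- matrix(0, 4, 4); P[, 3] <- 1
  cfg <- eeg_sim_config(duration_s = 300, state_transition_matrix = P,
                        rng_seed = 3)
  sim <- simulate_eeg(cfg)
  expect_true(all(sim$truth$hypnogram$labels == "SWS"))
})

test_that("a non-stochastic transition matrix is rejected", {
  P <- matrix(0.3, 4, 4)
  expect_error(eeg_sim_config(state_transition_matrix = P), "row-stochastic")
})

test_that("doubling the delta amplitude quadruples delta-band power", {
  prof <- default_state_profile()
  prof$theta_amp <- rep(0, 4); prof$broadband_amp <- rep(0, 4)
  prof$delta_amp <- rep(20, 4)
  prof2 <- prof; prof2$delta_amp <- rep(40, 4)
  cfg1 <- eeg_sim_config(duration_s = 120, state_profile = prof,
                         spike_train_rate_per_hour = 0, rng_seed = 5)
  cfg2 <- eeg_sim_config(duration_s = 120, state_profile = prof2,
                         spike_train_rate_per_hour = 0, rng_seed = 5)
  p1 <- band_power(compute_psd(simulate_eeg(cfg1)$recording))
  p2 <- band_power(compute_psd(simulate_eeg(cfg2)$recording))
  ratio <- p2$power_uV2[p2$band == "delta"] / p1$power_uV2[p1$band == "delta"]
  expect_equal(ratio, 4, tolerance = 0.1)
})

test_that("the same seed reproduces a recording exactly; different seeds differ", {
  cfg <- eeg_sim_config(duration_s = 60, rng_seed = 7)
  a <- simulate_eeg(cfg); b <- simulate_eeg(cfg)
  expect_identical(a$recording$eeg, b$recording$eeg)
  expect_identical(a$truth$hypnogram$labels, b$truth$hypnogram$labels)
  cfg2 <- cfg; cfg2$rng_seed <- 8
  c <- simulate_eeg(cfg2)
  expect_false(identical(a$recording$eeg, c$recording$eeg))

  mcfg <- mea_sim_config(n_electrodes = 1000L, n_active_electrodes = 100L,
                         duration_s = 60, rng_seed = 7)
  ra <- simulate_raster(mcfg); rb <- simulate_raster(mcfg)
  expect_identical(ra$raster$events, rb$raster$events)
})

test_that("long-run state occupancy converges to the stationary distribution", {
  pi0 <- c(0.15, 0.25, 0.45, 0.15)
  rho <- 0.6
  cfg <- eeg_sim_config(
    duration_s = 7200, epoch_len_s = 10,
    state_transition_matrix = sticky_transition_matrix(pi0, rho),
    spike_train_rate_per_hour = 0, rng_seed = 11
  )
  sim <- simulate_eeg(cfg)
  occ <- as.numeric(table(factor(sim$truth$hypnogram$labels,
                                 levels = SLEEP_STATES))) /
    length(sim$truth$hypnogram$labels)
  # effective sample size of a sticky chain: n (1-rho)/(1+rho)
  n_eff <- 720 * (1 - rho) / (1 + rho)
  se <- sqrt(pi0 * (1 - pi0) / n_eff)
  expect_true(all(abs(occ - pi0) <= 3 * se))
})

test_that("Poisson-placed train counts pass a chi-square goodness-of-fit", {
  # rate 150/h over 120 s -> mean 5 trains per replicate
  lambda <- 150 * 120 / 3600
  set.seed(13)
  counts <- vapply(seq_len(200), function(i) {
    cfg <- flat_eeg_config(120, n_trains = NULL, seed = NULL)
    cfg$spike_train_rate_per_hour <- 150
    nrow(simulate_eeg(cfg)$truth$spike_trains)
  }, numeric(1))
  breaks <- c(-0.5, 2.5, 3.5, 4.5, 5.5, 6.5, 7.5, Inf)
  obs <- table(cut(counts, breaks))
  p <- diff(ppois(breaks, lambda))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = p / sum(p)))
  expect_gt(gof$p.value, 0.01)
})

test_that("raster generator matches its Poisson and burst arithmetic", {
  cfg <- mea_sim_config(n_electrodes = 1000L, n_active_electrodes = 100L,
                        duration_s = 300, baseline_rate_hz = 1,
                        burst_rate_per_min = 0, rng_seed = 17)
  sim <- simulate_raster(cfg)
  expect_equal(nrow(sim$truth$bursts), 0)
  # total events ~ Poisson(30000)
  expect_lt(abs(nrow(sim$raster$events) - 30000), 4 * sqrt(30000))

  cfg2 <- mea_sim_config(n_electrodes = 500L, n_active_electrodes = 100L,
                         duration_s = 300, baseline_rate_hz = 1,
                         burst_rate_per_min = 2, burst_duration_s = 0.3,
                         within_burst_rate_multiplier = 20,
                         electrode_participation_prob = 1, rng_seed = 19)
  sim2 <- simulate_raster(cfg2)
  tru <- sim2$truth$bursts
  expect_gt(nrow(tru), 0)
  ev <- sim2$raster$events$spike_time_s
  base_rate <- 100 * 1   # pooled baseline spikes/s
  for (i in seq_len(nrow(tru))) {
    n_in <- sum(ev >= tru$onset_s[i] & ev <= tru$offset_s[i])
    rate_in <- n_in / (tru$offset_s[i] - tru$onset_s[i])
    expect_gt(rate_in, 5 * base_rate)
  }
})

test_that("genotype presets encode the mutant directions and are deterministic", {
  wt <- genotype_preset("WT"); het <- genotype_preset("HET")
  expect_gt(het$eeg$spike_train_rate_per_hour, wt$eeg$spike_train_rate_per_hour)
  expect_gt(mean(het$eeg$spikes_per_train_range),
            mean(wt$eeg$spikes_per_train_range))
  pi_wt <- markov_stationary(wt$eeg$state_transition_matrix)
  pi_het <- markov_stationary(het$eeg$state_transition_matrix)
  expect_lt(pi_het[3], pi_wt[3])   # SWS down
  expect_gt(pi_het[1], pi_wt[1])   # active wake up
  expect_gt(het$mea$burst_rate_per_min, wt$mea$burst_rate_per_min)
  expect_lt(het$mea$within_burst_rate_multiplier,
            wt$mea$within_burst_rate_multiplier)
  expect_identical(genotype_preset("WT"), genotype_preset("WT"))
  expect_error(genotype_preset("KO"), "unknown preset")
})

test_that("sim configs round trip through JSON", {
  cfg <- mea_sim_config(n_electrodes = 200L, n_active_electrodes = 50L,
                        duration_s = 60, rng_seed = 21)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(c(list(kind = "mea"), unclass(cfg)), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  back <- read_sim_config(path)
  expect_s3_class(back, "mea_sim_config")
  expect_equal(back$burst_rate_per_min, cfg$burst_rate_per_min)
})
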