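tiny_raster <- function(ids, times, n_el = 10L, dur = 300) {
  spike_raster(data.frame(electrode_id = as.integer(ids),
                          spike_time_s = times),
               n_electrodes = n_el, duration_s = dur)
}

test_that("activity scan computes per-electrode rates", {
  r <- tiny_raster(c(rep(2L, 60), rep(7L, 3)),
                   c(runif(60, 0, 30), runif(3, 0, 30)))
  scan <- activity_scan(r, 30)
  expect_equal(nrow(scan), 10)
  expect_equal(scan$rate_hz[scan$electrode_id == 2], 2)
  expect_equal(scan$rate_hz[scan$electrode_id == 0], 0)

  sim <- simulate_raster(mea_sim_config(
    n_electrodes = 26400L, n_active_electrodes = 1000L, duration_s = 30,
    baseline_rate_hz = 1, burst_rate_per_min = 0, rng_seed = 101))
  scan <- activity_scan(sim$raster, 30)
  act_rates <- scan$rate_hz[scan$electrode_id %in%
                              sim$truth$active_electrodes]
  se <- sqrt(1 / 30) / sqrt(1000)
  expect_lt(abs(mean(act_rates) - 1), 3 * se)
})

test_that("top-electrode selection ranks by rate with id tie-break", {
  scan <- data.frame(electrode_id = 0:3, rate_hz = c(5, 3, 3, 1))
  expect_equal(select_top_electrodes(scan, 2), c(0L, 1L))

  zero <- data.frame(electrode_id = 0:9, rate_hz = rep(0, 10))
  expect_warning(sel <- select_top_electrodes(zero, 1024), "only 0")
  expect_length(sel, 0)
  expect_error(select_top_electrodes(scan, 0), "n must be")

  sim <- simulate_raster(mea_sim_config(
    n_electrodes = 5000L, n_active_electrodes = 200L, duration_s = 30,
    baseline_rate_hz = 2, burst_rate_per_min = 0, rng_seed = 103))
  scan <- activity_scan(sim$raster, 30)
  fired <- sort(unique(sim$raster$events$electrode_id))
  sel <- suppressWarnings(select_top_electrodes(scan, length(fired)))
  expect_equal(sel, fired)
})

test_that("the network trace matches the Gaussian closed form and conserves spikes", {
  r <- tiny_raster(0L, 150)
  tr <- network_trace(r, kernel_sigma_s = 0.1, dt = 0.01)
  expect_equal(tr$time_s[which.max(tr$rate)], 150, tolerance = 0.011)
  expect_equal(max(tr$rate), 1 / (0.1 * sqrt(2 * pi)), tolerance = 0.01)

  empty <- tiny_raster(integer(0), numeric(0))
  expect_true(all(network_trace(empty)$rate == 0))

  set.seed(107)
  r2 <- tiny_raster(sample(0:9, 5000, replace = TRUE),
                    runif(5000, 1, 299), dur = 300)
  tr2 <- network_trace(r2, kernel_sigma_s = 0.05, dt = 0.01)
  expect_equal(sum(tr2$rate) * tr2$dt, 5000, tolerance = 0.01)

  expect_error(network_trace(r, kernel_sigma_s = 0.05, dt = 0.05), "dt must")
})

test_that("burst detection handles degenerate traces and a lone burst", {
  empty <- tiny_raster(integer(0), numeric(0))
  tr <- network_trace(empty)
  expect_equal(nrow(detect_bursts(tr, empty)), 0)

  # all activity is one planted burst, no background
  ids <- rep(0:49, each = 20)
  times <- rep(seq(30, 30.3, length.out = 20), times = 50)
  r <- tiny_raster(ids, times, n_el = 100L, dur = 60)
  tr <- network_trace(r, kernel_sigma_s = 0.05, dt = 0.01)
  b <- detect_bursts(tr, r)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_spikes, 1000)
  expect_true(b$onset_s <= 30 && b$offset_s >= 30.3)
})

test_that("planted bursts are recovered with perfect precision and recall", {
  cfg <- mea_sim_config(n_electrodes = 2000L, n_active_electrodes = 256L,
                        duration_s = 300, baseline_rate_hz = 1,
                        burst_rate_per_min = 4, burst_duration_s = 0.3,
                        within_burst_rate_multiplier = 20,
                        electrode_participation_prob = 1, rng_seed = 113)
  sim <- simulate_raster(cfg)
  tr <- network_trace(sim$raster, kernel_sigma_s = 0.05, dt = 0.01)
  b <- detect_bursts(tr, sim$raster)
  truth <- sim$truth$bursts
  hits <- match_bursts(b$peak_time_s, truth, tol_s = 0.5 * 0.3)
  expect_equal(hits, nrow(truth))      # recall 1
  expect_equal(nrow(b), nrow(truth))   # precision 1
})

test_that("raising the threshold multiplier never adds bursts", {
  sim <- simulate_raster(mea_sim_config(
    n_electrodes = 2000L, n_active_electrodes = 256L, duration_s = 300,
    baseline_rate_hz = 1, burst_rate_per_min = 4,
    within_burst_rate_multiplier = 8, rng_seed = 127))
  tr <- network_trace(sim$raster, kernel_sigma_s = 0.05, dt = 0.01)
  n <- vapply(c(2, 5, 10, 20, 50),
              function(k) nrow(detect_bursts(tr, sim$raster, k = k)),
              numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("dilating time and sigma rescales intervals and keeps counts", {
  cfg <- mea_sim_config(n_electrodes = 500L, n_active_electrodes = 64L,
                        duration_s = 300, baseline_rate_hz = 0.5,
                        burst_rate_per_min = 3,
                        within_burst_rate_multiplier = 25,
                        electrode_participation_prob = 1, rng_seed = 131)
  sim <- simulate_raster(cfg)
  r1 <- sim$raster
  c_fac <- 3
  r2 <- spike_raster(
    data.frame(electrode_id = r1$events$electrode_id,
               spike_time_s = r1$events$spike_time_s * c_fac),
    n_electrodes = 500L, duration_s = 300 * c_fac)
  tr1 <- network_trace(r1, kernel_sigma_s = 0.05, dt = 0.01)
  tr2 <- network_trace(r2, kernel_sigma_s = 0.05 * c_fac, dt = 0.01 * c_fac)
  b1 <- detect_bursts(tr1, r1)
  b2 <- detect_bursts(tr2, r2)
  expect_equal(nrow(b1), nrow(b2))
  m1 <- burst_metrics(b1); m2 <- burst_metrics(b2)
  expect_equal(m2$inter_burst_interval_s, c_fac * m1$inter_burst_interval_s,
               tolerance = 0.02)
  expect_equal(m2$burst_duration_s, c_fac * m1$burst_duration_s,
               tolerance = 0.05)
})

test_that("burst metrics and DIV trajectories do their arithmetic", {
  b <- data.frame(onset_s = c(9, 19, 39), peak_time_s = c(10, 20, 40),
                  offset_s = c(11, 21, 41), duration_s = c(2, 2, 2),
                  n_spikes = c(100, 200, 300), peak_rate = c(1, 2, 3))
  m <- burst_metrics(b, div = 21, chip_id = "c1")
  expect_equal(m$inter_burst_interval_s, 15)
  expect_equal(m$spikes_per_burst, 200)

  m1 <- burst_metrics(b[1, ], div = 17, chip_id = "c1")
  expect_true(is.na(m1$inter_burst_interval_s))
  expect_equal(m1$n_bursts, 1)

  stack <- rbind(
    burst_metrics(b, 17, "c1", "WT"), burst_metrics(b, 17, "c2", "WT"),
    burst_metrics(b, 21, "c1", "WT"), burst_metrics(b, 21, "c2", "WT"),
    burst_metrics(b, 17, "c3", "HET"), burst_metrics(b, 17, "c4", "HET"),
    burst_metrics(b, 21, "c3", "HET"), burst_metrics(b, 21, "c4", "HET")
  )
  traj <- div_trajectory(stack)
  expect_equal(nrow(traj), 2 * 2 * 4)      # group x div x metric
  expect_true(all(traj$n_chips == 2))
  single <- div_trajectory(burst_metrics(b, 17, "c1", "WT"))
  expect_true(all(is.na(single$sem)))
})
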