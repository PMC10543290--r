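test_that("flat or empty signals yield no spikes, with a warning when flat", {
  rec <- signal_recording(eeg = numeric(5000), emg = numeric(5000),
                          duration_s = 10)
  expect_warning(sp <- detect_spikes(rec), "flat")
  expect_equal(nrow(sp), 0)
  expect_equal(nrow(group_spike_trains(sp)), 0)
})

test_that("planted transients are each recovered within 50 ms", {
  sim <- simulate_eeg(flat_eeg_config(200, n_trains = 20, amp = 200,
                                      seed = 47, spikes_range = c(1L, 1L)))
  truth <- sim$truth$spike_trains
  sp <- detect_spikes(sim$recording, threshold_sd = 5)
  expect_equal(nrow(sp), 20)
  err <- vapply(truth$onset_s,
                function(t0) min(abs(sp$time_s - t0)), numeric(1))
  expect_lt(max(err), 0.05)
})

test_that("the refractory rule keeps the larger of two close events", {
  fs <- 500
  x <- rnorm(10 * fs, sd = 1)
  w <- ephyspheno:::spike_waveform(fs)   # internal biphasic template
  add <- function(x, t0, amp) {
    i <- round(t0 * fs); x[i:(i + length(w) - 1)] <- amp * w; x
  }
  x <- add(x, 5, 60)
  x <- add(x, 5.01, 100)         # 10 ms later, larger
  rec <- signal_recording(eeg = x, emg = numeric(length(x)),
                          duration_s = 10)
  sp <- detect_spikes(rec, threshold_sd = 5, refractory_s = 0.1)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$time_s, 5.01 + 0.01, tolerance = 0.05)
})

test_that("spike trains are grouped by gap and filtered by size", {
  spikes <- data.frame(time_s = c(0, 0.5, 1, 10),
                       amplitude_uV = c(1, 1, 1, 1) * 100)
  tr <- group_spike_trains(spikes, max_gap_s = 1, min_spikes = 2)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$onset_s, 0)
  expect_equal(tr$offset_s, 1)
  expect_equal(tr$n_spikes, 3)

  expect_equal(nrow(group_spike_trains(
    data.frame(time_s = numeric(0), amplitude_uV = numeric(0)))), 0)
})

test_that("grouping matches an independent transitive-closure oracle", {
  set.seed(53)
  for (rep in 1:20) {
    n <- sample(2:20, 1)
    times <- sort(runif(n, 0, 30))
    gap <- runif(1, 0.5, 3)
    tr <- group_spike_trains(data.frame(time_s = times), max_gap_s = gap,
                             min_spikes = 1)
    comp <- oracle_cluster(times, gap)
    expect_equal(nrow(tr), length(unique(comp)))
    sizes <- sort(as.numeric(table(comp)))
    expect_equal(sort(tr$n_spikes), sizes)
    # partition: every spike in exactly one train
    expect_equal(sum(tr$n_spikes), n)
  }
})

test_that("detection and grouping respond monotonically to their parameters", {
  sim <- simulate_eeg(flat_eeg_config(600, n_trains = 5, amp = 150,
                                      seed = 59))
  rec <- sim$recording
  counts <- vapply(c(3, 5, 8, 12),
                   function(th) nrow(detect_spikes(rec, threshold_sd = th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))

  sp <- detect_spikes(rec, threshold_sd = 4)
  n_by_gap <- vapply(c(0.3, 1, 2, 5), function(g)
    nrow(group_spike_trains(sp, max_gap_s = g, min_spikes = 1)), numeric(1))
  expect_true(all(diff(n_by_gap) <= 0))
  n_by_min <- vapply(c(1, 2, 3, 5), function(m)
    nrow(group_spike_trains(sp, max_gap_s = 2, min_spikes = m)), numeric(1))
  expect_true(all(diff(n_by_min) <= 0))
})

test_that("planted trains are recovered with their count and durations", {
  for (seed in c(61, 67)) {
    sim <- simulate_eeg(flat_eeg_config(600, n_trains = 5, amp = 200,
                                        seed = seed))
    sp <- detect_spikes(sim$recording, threshold_sd = 5)
    tr <- group_spike_trains(sp, max_gap_s = 2, min_spikes = 3)
    truth <- sim$truth$spike_trains
    expect_equal(nrow(tr), nrow(truth))
    err <- abs(tr$duration_s - (truth$offset_s - truth$onset_s))
    expect_lt(mean(err), 0.1)
  }
})

test_that("the train summary reports counts, rates and durations", {
  s0 <- spike_train_summary(group_spike_trains(
    data.frame(time_s = numeric(0))), 72 * 3600)
  expect_equal(s0$train_count, 0)
  expect_equal(s0$trains_per_hour, 0)
  expect_true(is.na(s0$mean_duration_s))
  expect_equal(s0$total_spikes, 0)

  tr <- data.frame(onset_s = seq(0, 3000, by = 600)[1:6],
                   offset_s = seq(0, 3000, by = 600)[1:6] + 1,
                   n_spikes = rep(4L, 6), duration_s = rep(1, 6))
  s <- spike_train_summary(tr, 3600)
  expect_equal(s$trains_per_hour, 6)
  expect_equal(s$mean_duration_s, 1)
  expect_equal(s$total_spikes, 24)
})
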