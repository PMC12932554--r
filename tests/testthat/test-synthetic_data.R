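test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- synth_config(duration_s = 10, sample_rate_hz = 500, n_channels = 4,
                      burst_rate = 12, peaks_per_burst = 3,
                      intra_burst_interval_s = 0.5, seed = 77)
  s1 <- simulate_recording(cfg)
  s2 <- simulate_recording(cfg)
  expect_identical(lapply(s1$recording$traces, `[[`, "samples"),
                   lapply(s2$recording$traces, `[[`, "samples"))
  expect_identical(s1$truth$cp_times_s, s2$truth$cp_times_s)
  s3 <- simulate_recording(synth_config(duration_s = 10, sample_rate_hz = 500,
                                        n_channels = 4, burst_rate = 12,
                                        peaks_per_burst = 3,
                                        intra_burst_interval_s = 0.5,
                                        seed = 78))
  expect_false(identical(s1$truth$cp_times_s, s3$truth$cp_times_s))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- rnorm(3)
  set.seed(99)
  suppressWarnings(simulate_recording(synth_config(duration_s = 2,
                                                   sample_rate_hz = 200,
                                                   n_channels = 1, seed = 5)))
  b <- rnorm(3)
  expect_identical(a, b)
})

test_that("noise-free pulses are recovered exactly at default-style params", {
  cfg <- synth_config(duration_s = 60, sample_rate_hz = 1000, n_channels = 1,
                      burst_rate = 2, peaks_per_burst = 3,
                      intra_burst_interval_s = 2, cp_width_s = 0.01,
                      noise_sigma = 0, channel_gains = 1, seed = 3)
  sim <- simulate_recording(cfg)
  expect_gt(length(sim$truth$cp_times_s), 0)
  p <- detection_params(normalized_threshold = 0.3, average_window = 20,
                        time_threshold = 0.02, refractory_period = 0.5)
  st <- preprocess_trace(sim$recording$traces[[1]], average_window = 20)
  train <- detect_peaks(st, p)
  expect_length(train$peak_times, length(sim$truth$cp_times_s))
  expect_true(all(abs(train$peak_times - sim$truth$cp_times_s) <=
                    p$time_threshold + 1e-9))
})

test_that("ground-truth metrics satisfy the tiling invariant", {
  for (s in 1:5) {
    cfg <- synth_config(duration_s = 120, sample_rate_hz = 200, n_channels = 1,
                        burst_rate = 4, peaks_per_burst = 4, cp_width_s = 0.02,
                        intra_burst_interval_s = 1.5, seed = s)
    tm <- simulate_recording(cfg)$truth$true_metrics
    expect_equal(tm$ctime + tm$etime, tm$t_last, tolerance = 1e-12)
  }
})

test_that("ascending channel gains put the best SNR on the last channel", {
  ok <- sapply(1:20, function(s) {
    cfg <- synth_config(duration_s = 20, sample_rate_hz = 1000, n_channels = 5,
                        burst_rate = 9, peaks_per_burst = 3, cp_width_s = 0.01,
                        intra_burst_interval_s = 1, noise_sigma = 0.1,
                        channel_gains = c(0.3, 0.6, 1.0, 1.5, 2.2), seed = s)
    sim <- simulate_recording(cfg)
    select_best_channel(sim$recording, snr_window = 20) == 4L
  })
  expect_gte(mean(ok), 0.95)
})

test_that("a too-short recording warns about empty ground truth", {
  cfg <- synth_config(duration_s = 0.5, sample_rate_hz = 200, n_channels = 1,
                      burst_rate = 0.5, seed = 2)
  expect_warning(sim <- simulate_recording(cfg), "too short")
  expect_length(sim$truth$cp_times_s, 0)
  expect_null(sim$truth$true_metrics)
})

test_that("analytic expectations match the programmed configuration", {
  cfg <- synth_config_hyai(0.5, duration_s = 600)
  ea <- expected_activity(cfg)
  expect_equal(ea$hyai, 0.5, tolerance = 1e-12)
  # mean planted count agrees with the renewal expectation over seeds
  cfg_fast <- synth_config(duration_s = 300, sample_rate_hz = 100,
                           n_channels = 1, burst_rate = 6,
                           peaks_per_burst = 5, intra_burst_interval_s = 0.5,
                           cp_width_s = 0.02, noise_sigma = 0)
  counts <- sapply(1:30, function(s) {
    cfg_fast$seed <- s
    length(simulate_recording(cfg_fast)$truth$cp_times_s)
  })
  expect_equal(mean(counts), expected_activity(cfg_fast)$n_cp_mean,
               tolerance = 0.1)
})

test_that("rhythmic potentials stay below the detection threshold", {
  cfg <- synth_config(duration_s = 60, sample_rate_hz = 1000, n_channels = 1,
                      burst_rate = 2, peaks_per_burst = 3, cp_width_s = 0.01,
                      intra_burst_interval_s = 2, noise_sigma = 0.05,
                      rp_amplitude = 0.15, rp_rate_hz = 0.3,
                      channel_gains = 1, seed = 17)
  sim <- simulate_recording(cfg)
  expect_gt(length(sim$truth$rp_times_s), 0)
  p <- detection_params(normalized_threshold = 0.3, average_window = 20,
                        time_threshold = 0.02, refractory_period = 0.5)
  st <- preprocess_trace(sim$recording$traces[[1]], average_window = 20)
  train <- detect_peaks(st, p)
  m <- match_events(train$peak_times, sim$truth$cp_times_s, tol = 0.025)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})
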