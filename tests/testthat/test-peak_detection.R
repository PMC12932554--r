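test_that("centred first difference is exact on affine signals", {
  t <- seq(0, 1, by = 0.01)
  d <- first_derivative(3 * t + 2, dt = 0.01, theta = 0.02)
  expect_true(all(is.na(d[c(1, length(d))])))
  expect_equal(unique(round(d[!is.na(d)], 12)), 3)
  expect_equal(unique(first_derivative(rep(5, 50), 0.01, 0.04) |>
                        na.omit() |> as.numeric()), 0)
})

test_that("composed second difference is exact on quadratics", {
  t <- seq(0, 1, by = 0.01)
  f1 <- first_derivative(t^2, dt = 0.01, theta = 0.02)
  f2 <- second_derivative(f1, dt = 0.01, theta = 0.02)
  expect_equal(unique(round(f2[!is.na(f2)], 10)), 2)
  f1l <- first_derivative(7 * t, dt = 0.01, theta = 0.02)
  f2l <- second_derivative(f1l, dt = 0.01, theta = 0.02)
  expect_equal(unique(round(f2l[!is.na(f2l)], 10)), 0)
})

test_that("derivative error on a sinusoid is second order in theta", {
  dt <- 1e-3
  t <- seq(0, 2, by = dt)
  x <- sin(2 * pi * t)
  f1 <- first_derivative(x, dt, theta = 2e-3)
  f2 <- second_derivative(f1, dt, theta = 2e-3)
  interior <- 5:(length(t) - 4)
  expect_lt(max(abs(f1[interior] - 2 * pi * cos(2 * pi * t[interior]))), 1e-3)
  expect_lt(max(abs(f2[interior] + (2 * pi)^2 * sin(2 * pi * t[interior]))),
            5e-2)
})

test_that("theta must align with the sample grid", {
  expect_error(first_derivative(1:100, dt = 0.01, theta = 0.01), "even number")
  expect_error(first_derivative(1:100, dt = 0.01, theta = 0.031), "even number")
  expect_error(first_derivative(1:3, dt = 0.01, theta = 0.1), "too short")
})

test_that("a single planted pulse is recovered at its apex, gated by threshold", {
  tr <- pulse_trace(5, height = 0.9, width = 0.008, duration = 10, sr = 1000)
  st <- preprocess_trace(tr, average_window = 20)
  p <- detection_params(normalized_threshold = 0.3, average_window = 20,
                        time_threshold = 0.02, refractory_period = 0.3)
  train <- detect_peaks(st, p)
  expect_length(train$peak_times, 1)
  expect_lt(abs(train$peak_times - 5), p$time_threshold + 1e-9)

  p95 <- detection_params(normalized_threshold = 0.95, average_window = 20,
                          time_threshold = 0.02)
  expect_length(detect_peaks(st, p95)$peak_times, 0)
})

test_that("refractory spacing holds and threshold monotonicity is respected", {
  cfg <- synth_config(duration_s = 60, sample_rate_hz = 1000, n_channels = 1,
                      burst_rate = 6, peaks_per_burst = 4,
                      intra_burst_interval_s = 1, cp_width_s = 0.01,
                      noise_sigma = 0.08, channel_gains = 1, seed = 9)
  st <- preprocess_trace(simulate_recording(cfg)$recording$traces[[1]],
                         average_window = 20)
  counts <- sapply(c(0.1, 0.2, 0.3, 0.5, 0.7, 0.9), function(thr) {
    p <- detection_params(normalized_threshold = thr, average_window = 20,
                          time_threshold = 0.02, refractory_period = 0.3)
    train <- detect_peaks(st, p)
    if (length(train$peak_times) > 1)
      expect_gte(min(diff(train$peak_times)), p$refractory_period)
    length(train$peak_times)
  })
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], 0)
})

test_that("noise-free pulse trains match a brute-force local-max oracle", {
  apexes <- c(1.5, 3.0, 4.2, 6.8, 8.1)
  tr <- pulse_trace(apexes, height = 0.9, width = 0.008, duration = 10,
                    sr = 1000, noise = 0)
  st <- preprocess_trace(tr, average_window = 20)
  p <- detection_params(normalized_threshold = 0.3, average_window = 20,
                        time_threshold = 0.02, refractory_period = 0.3)
  train <- detect_peaks(st, p)
  oracle <- local_max_oracle(st$signal_mean, st$times,
                             threshold = 0.3, dead_time = 0.3)
  expect_length(train$peak_times, length(oracle))
  expect_true(all(abs(train$peak_times - oracle) <= p$time_threshold + 1e-9))
})

test_that("detection recovers planted pulses in noise", {
  hits <- sapply(1:10, function(s) {
    cfg <- synth_config(duration_s = 60, sample_rate_hz = 1000,
                        n_channels = 1, burst_rate = 5, peaks_per_burst = 4,
                        intra_burst_interval_s = 2, intra_burst_cv = 0.2,
                        cp_width_s = 0.01, noise_sigma = 1 / 6,
                        channel_gains = 1, seed = 100 + s)
    sim <- simulate_recording(cfg)
    p <- detection_params(normalized_threshold = 0.3, average_window = 20,
                          time_threshold = 0.02, refractory_period = 0.3)
    st <- preprocess_trace(sim$recording$traces[[1]], average_window = 20)
    train <- detect_peaks(st, p)
    m <- match_events(train$peak_times, sim$truth$cp_times_s, tol = 0.025)
    m$precision >= 0.95 && m$recall >= 0.95
  })
  expect_gte(sum(hits), 9)
})
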