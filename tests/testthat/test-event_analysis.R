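test_that("alignment zeroes the first peak and takes the minimum window", {
  p <- detection_params()
  a <- align_trains(list(make_train(c(12, 50, 100), 600),
                         make_train(c(30, 80), 595.519)))
  expect_equal(a$t_last, 565.519)
  expect_equal(a$trains[[1]][1], 0)
  expect_equal(a$trains[[2]], c(0, 50))
  expect_equal(a$dropped_prefix, c(12, 30))

  one <- align_trains(list(make_train(c(0, 5, 9), 20)))
  expect_equal(one$t_last, 20)
  expect_equal(one$trains[[1]], c(0, 5, 9))

  twin <- align_trains(list(make_train(c(3, 7), 50), make_train(c(3, 7), 50)))
  expect_identical(twin$trains[[1]], twin$trains[[2]])
})

test_that("alignment drops empty trains with a warning, t_last order-invariant", {
  trains <- list(make_train(c(4, 9), 30), make_train(numeric(0), 30),
                 make_train(c(1, 20), 28))
  expect_warning(a <- align_trains(trains), "zero peaks")
  expect_length(a$trains, 2)
  expect_error(align_trains(list(make_train(numeric(0), 5))), "empty")

  set.seed(8)
  tl <- replicate(5, {
    perm <- sample(trains[c(1, 3)])
    suppressWarnings(align_trains(perm)$t_last)
  })
  expect_equal(length(unique(tl)), 1L)
})

test_that("interval classification applies the threshold rule directly", {
  p <- detection_params(cp_threshold = 10)
  ev <- classify_intervals(c(0, 1, 2, 40), t_last = 80, params = p)
  expect_equal(as.character(ev$class), c("CP", "CP", "IcBI", "IcBI"))
  expect_equal(ev$duration_s, c(1, 1, 38, 40))
  expect_equal(ev$burst_index, c(1L, 1L, NA, NA))
  expect_equal(sum(ev$duration_s), 80)

  m <- compute_metrics(ev)
  expect_equal(m$n_burst, 1L)
  expect_equal(m$n_icbi, 2L)
  expect_equal(m$n_cp, 2L)
  expect_equal(m$ctime + m$etime, 80)
})

test_that("a lone peak yields one terminal CP interval and flagged HyAI", {
  p <- detection_params(cp_threshold = 10)
  ev <- classify_intervals(0, t_last = 5, params = p)
  expect_equal(nrow(ev), 1L)
  expect_equal(as.character(ev$class), "CP")
  m <- compute_metrics(ev)
  expect_equal(m$ctime, 5)
  expect_equal(m$etime, 0)
  expect_false(m$hyai_defined)
  expect_true(is.infinite(m$hyai))
})

test_that("unaligned or malformed trains are rejected", {
  p <- detection_params()
  expect_error(classify_intervals(c(1, 2), 10, p), "not aligned")
  expect_error(classify_intervals(c(0, 2, 2), 10, p), "strictly increase")
  expect_error(classify_intervals(c(0, 20), 10, p), "precedes")
})

test_that("classification and burst segmentation match the brute-force oracle", {
  set.seed(123)
  for (i in 1:200) {
    rt <- random_train(n_peaks = sample(2:40, 1), gap_scale = runif(1, 1, 10))
    thr <- runif(1, 0.5, 15)
    p <- detection_params(cp_threshold = thr)
    ev <- classify_intervals(rt$peaks, rt$t_last, p)
    oracle <- classify_oracle(rt$peaks, rt$t_last, thr)
    expect_identical(as.character(ev$class), oracle$class)
    expect_identical(ev$burst_index, oracle$burst_index)
    expect_equal(ev$duration_s, oracle$durations)
    # tiling conservation and the CTime/ETime split
    expect_lt(abs(sum(ev$duration_s) - rt$t_last), 1e-9 * rt$t_last)
    m <- compute_metrics(ev)
    expect_equal(m$ctime + m$etime, rt$t_last, tolerance = 1e-12)
    expect_equal(m$n_cp, sum(m$n_cp_burst))
    # idempotence
    ev2 <- classify_intervals(rt$peaks, rt$t_last, p)
    expect_identical(ev, ev2)
  }
})

test_that("distinct thresholds create an ambiguous band excluded from bursts", {
  p <- detection_params(cp_threshold = 5, icbi_threshold = 10)
  expect_warning(ev <- classify_intervals(c(0, 2, 9, 30), 60, p), "ambiguous")
  expect_equal(as.character(ev$class), c("CP", "ambiguous", "IcBI", "IcBI"))
  expect_true(is.na(ev$burst_index[2]))
  m <- compute_metrics(ev)
  expect_equal(m$ctime, 2)
  expect_equal(m$etime, 21 + 30)
})

test_that("metric arithmetic follows the activity-index definition", {
  p <- detection_params(cp_threshold = 15)
  # CP intervals 4+6 = 10 s, IcBI 40 s -> HyAI 0.25
  ev <- classify_intervals(c(0, 4, 10), t_last = 50,
                           params = detection_params(cp_threshold = 7))
  m <- compute_metrics(ev)
  expect_equal(m$ctime, 10)
  expect_equal(m$etime, 40)
  expect_equal(m$hyai, 0.25)

  # all intervals IcBI -> CTime 0, HyAI 0
  ev0 <- classify_intervals(c(0, 20, 45), t_last = 80,
                            params = detection_params(cp_threshold = 10))
  m0 <- compute_metrics(ev0)
  expect_equal(m0$ctime, 0)
  expect_equal(m0$hyai, 0)

  # adding a CP interval with ETime fixed strictly increases HyAI
  ev_more <- classify_intervals(c(0, 4, 8, 14), t_last = 54,
                                params = detection_params(cp_threshold = 7))
  m_more <- compute_metrics(ev_more)
  expect_equal(m_more$etime, m$etime)
  expect_gt(m_more$hyai, m$hyai)
})

test_that("count conventions differ by one peak per burst", {
  p <- detection_params(cp_threshold = 10)
  ev <- classify_intervals(c(0, 1, 2, 40, 41, 90), t_last = 120, params = p)
  mi <- compute_metrics(ev, count_convention = "intervals")
  mp <- compute_metrics(ev, count_convention = "peaks")
  expect_equal(mi$n_cp_burst, c(2L, 1L))
  expect_equal(mp$n_cp_burst, c(3L, 2L))
  expect_equal(mp$n_cp - mi$n_cp, mi$n_burst)
})

test_that("raster reflects trains and stays inside the window", {
  a <- align_trains(list(make_train(c(2, 5, 9), 20),
                         make_train(c(1, 3, 18), 22)))
  r <- raster(a)
  expect_equal(attr(r, "n_trains"), 2L)
  expect_equal(unname(table(r$train)), c(3L, 3L), ignore_attr = TRUE)
  expect_true(all(r$time_s <= a$t_last))

  cfg <- synth_config(duration_s = 30, sample_rate_hz = 200, n_channels = 1,
                      burst_rate = 8, peaks_per_burst = 3, cp_width_s = 0.05,
                      intra_burst_interval_s = 1, noise_sigma = 0,
                      channel_gains = 1)
  trains <- lapply(1:10, function(s) {
    cfg$seed <- s
    make_train(simulate_recording(cfg)$truth$cp_times_s, 30,
               source_id = paste0("r", s))
  })
  r10 <- raster(align_trains(trains))
  expect_equal(attr(r10, "n_trains"), 10L)
  expect_true(all(r10$time_s <= attr(r10, "t_last") + 1e-12))
})
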