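test_that("the generator is deterministic under its seed", {
  cfg <- simulation_config(n_nights = 1, sample_rate_hz = 5, seed = 21)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording, b$recording)
  expect_identical(a$truth$nights, b$truth$nights)
  cfg2 <- simulation_config(n_nights = 1, sample_rate_hz = 5, seed = 22)
  expect_false(identical(simulate_recording(cfg2)$recording$x, a$recording$x))
  # the log and hypnogram are reproducible too
  expect_identical(simulate_sleep_log(a$truth, cfg), simulate_sleep_log(b$truth, cfg))
  expect_identical(simulate_hypnogram(a$truth, cfg)$stage,
                   simulate_hypnogram(b$truth, cfg)$stage)
})

test_that("a motionless noise-free recording yields one bout spanning it", {
  cfg <- simulation_config(
    n_nights = 1, sample_rate_hz = 5, seed = 23, noise_sd_g = 0,
    wake_posture_dwell_s = 1e9, wake_dwell_max_s = 2e9,
    sleep_posture_dwell_min = 1e9, sleep_dwell_min_min = 1,
    move_on_transition = FALSE
  )
  sim <- simulate_recording(cfg)
  ang <- compute_angle_series(sim$recording)
  expect_lt(diff(range(ang$angle_deg)), 1e-9)
  bouts <- detect_bouts(ang)
  expect_equal(nrow(bouts), 1L)
  expect_equal(bouts$duration_min, nrow(ang) * 5 / 60)
})

test_that("wake periods churn and sleep periods are still, by construction", {
  cfg <- simulation_config(n_nights = 1, sample_rate_hz = 5, seed = 24)
  sim <- simulate_recording(cfg)
  ang <- compute_angle_series(sim$recording)
  tr <- sim$truth$nights
  asleep <- ang$epoch_start >= tr$onset & ang$epoch_start + 5 <= tr$waking
  d <- abs(diff(ang$angle_deg))
  mid <- asleep[-1] & asleep[-length(asleep)]
  # posture changes while asleep are rare: far fewer supra-threshold steps
  rate_sleep <- mean(d[mid] > 5, na.rm = TRUE)
  rate_wake <- mean(d[!mid] > 5, na.rm = TRUE)
  expect_lt(rate_sleep, 0.01)
  expect_gt(rate_wake, 10 * rate_sleep)
})

test_that("noise-free error-free logs reproduce the truth to the minute", {
  cfg <- simulation_config(n_nights = 3, sample_rate_hz = 5, seed = 25,
                           log_jitter_sd_min = 0)
  sim <- simulate_recording(cfg)
  log <- simulate_sleep_log(sim$truth, cfg)
  expect_false(any(log$error_am_pm | log$error_swap))
  parsed <- parse_sleep_log(log[, c("date", "onset", "waking")])
  expect_true(all(abs(difftime(parsed$onset, sim$truth$nights$onset, units = "mins")) < 1))
  expect_true(all(abs(difftime(parsed$waking, sim$truth$nights$waking, units = "mins")) < 1))
})

test_that("injected swap errors are recorded and produce swapped clocks", {
  cfg <- simulation_config(n_nights = 4, sample_rate_hz = 5, seed = 26,
                           log_swap_p = 1, log_jitter_sd_min = 0)
  sim <- simulate_recording(cfg)
  log <- simulate_sleep_log(sim$truth, cfg)
  expect_true(all(log$error_swap))
  truth_onset_clock <- format(sim$truth$nights$onset, "%H:%M")
  expect_equal(log$waking, truth_onset_clock)
})

test_that("simulated hypnograms honour the wake-insertion rate", {
  cfg0 <- simulation_config(n_nights = 1, sample_rate_hz = 5, seed = 27,
                            psg_wake_block_p = 0)
  sim <- simulate_recording(cfg0)
  hyp0 <- simulate_hypnogram(sim$truth, cfg0)
  expect_false(any(hyp0$stage == "W"))
  expect_equal(attr(hyp0, "lights_out"), sim$truth$nights$onset)

  cfg1 <- simulation_config(n_nights = 1, sample_rate_hz = 5, seed = 27,
                            psg_wake_block_p = 0.1)
  hyp1 <- simulate_hypnogram(simulate_recording(cfg1)$truth, cfg1)
  expect_gt(mean(hyp1$stage == "W"), 0.05)
  # an always-sleep predictor cannot reach perfect specificity here
  span <- one_bout <- tibble::tibble(
    bout_id = 1L,
    start = attr(hyp1, "lights_out"), end = attr(hyp1, "wake_up"),
    duration_min = as.numeric(difftime(attr(hyp1, "wake_up"),
                                       attr(hyp1, "lights_out"), units = "mins"))
  )
  m <- classification_metrics(epoch_classification(span, hyp1))
  expect_equal(m$sensitivity_pct, 100)
  expect_equal(m$specificity_pct, 0)
})

test_that("naps appear as daytime inactivity and are excluded by the log window", {
  cfg <- simulation_config(n_nights = 1, sample_rate_hz = 5, seed = 28,
                           nap_rate = 3)
  sim <- simulate_recording(cfg)
  expect_gt(nrow(sim$truth$naps), 0) # Poisson(3) draw under this fixed seed
  bouts <- detect_bouts(compute_angle_series(sim$recording))
  tr <- sim$truth$nights
  noct <- classify_nocturnal(bouts, tr$onset, tr$waking)
  daytime <- dplyr::anti_join(bouts, noct, by = "bout_id")
  expect_gt(nrow(daytime), 0L)
  # daytime bouts overlap the simulated nap intervals
  nap_overlap <- vapply(seq_len(nrow(daytime)), function(i) {
    any(daytime$start[i] < sim$truth$naps$end & daytime$end[i] > sim$truth$naps$start)
  }, logical(1))
  expect_true(all(nap_overlap))
})

test_that("simulated fixtures round-trip through the CSV readers", {
  cfg <- simulation_config(n_nights = 1, sample_rate_hz = 0.2, seed = 29)
  sim <- simulate_recording(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  raw <- read_raw_csv(file.path(dir, "raw.csv"))
  expect_equal(nrow(raw), nrow(sim$recording))
  expect_equal(as.numeric(raw$timestamp), as.numeric(sim$recording$timestamp))
  expect_equal(raw$x, sim$recording$x)
  expect_equal(raw$z, sim$recording$z)
  log <- parse_sleep_log(file.path(dir, "sleep_log.csv"))
  expect_equal(nrow(log), 1L)
  hyp <- read_hypnogram(file.path(dir, "hypnogram.csv"))
  expect_s3_class(hyp, "hypnogram")
})
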