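test_that("log entries resolve onto the calendar by the evening/morning rules", {
  log <- parse_sleep_log(data.frame(
    date = c("2013-02-07", "2013-02-08", "2013-02-09"),
    onset = c("23:30", "00:45", "11:30 PM"),
    waking = c("07:15", "06:50", "6:50 AM")
  ))
  expect_equal(log$onset[1], t_utc("2013-02-07 23:30:00"))
  expect_equal(log$waking[1], t_utc("2013-02-08 07:15:00"))
  # after-midnight onset belongs to the next date (inside the noon-noon window)
  expect_equal(log$onset[2], t_utc("2013-02-09 00:45:00"))
  expect_equal(log$waking[2], t_utc("2013-02-09 06:50:00"))
  # AM/PM notation
  expect_equal(log$onset[3], t_utc("2013-02-09 23:30:00"))
  expect_false(any(log$ambiguous))
  expect_true(all(log$waking > log$onset))
})

test_that("malformed rows are kept and flagged, duplicates rejected", {
  log <- parse_sleep_log(data.frame(
    date = c("2013-02-07", "2013-02-08"),
    onset = c("25:99", "23:00"),
    waking = c("07:00", "07:00")
  ))
  expect_true(log$ambiguous[1])
  expect_equal(log$reason[1], "unparseable time")
  expect_true(is.na(log$onset[1]))
  expect_false(log$ambiguous[2])
  expect_error(
    parse_sleep_log(data.frame(date = rep("2013-02-07", 2),
                               onset = c("23:00", "23:10"),
                               waking = c("07:00", "07:10"))),
    "duplicate"
  )
})

test_that("night windows are noon-noon, or 18:00-18:00 for day sleepers", {
  log <- assign_night_window(parse_sleep_log(data.frame(
    date = c("2013-02-07", "2013-02-08", "2013-02-09", "2013-02-10"),
    onset = c("23:30", "09:00", "11:59", "12:00"),
    waking = c("07:15", "16:30", "12:01", "18:00")
  )))
  expect_equal(log$window_kind, c("standard", "day_sleeper", "day_sleeper", "standard"))
  expect_equal(log$window_start[1], t_utc("2013-02-07 12:00:00"))
  expect_equal(log$window_end[1], t_utc("2013-02-08 12:00:00"))
  expect_equal(log$window_start[2], t_utc("2013-02-08 18:00:00"))
  expect_true(all(as.numeric(difftime(log$window_end, log$window_start, units = "hours")) == 24))
})

test_that("deviations are measured to the matched bout edges", {
  bouts <- tibble::tibble(
    bout_id = 1:2,
    start = t_utc(c("2013-02-07 23:20:00", "2013-02-08 03:00:00")),
    end = t_utc(c("2013-02-08 02:40:00", "2013-02-08 07:05:00")),
    duration_min = c(200, 245)
  )
  log <- parse_sleep_log(data.frame(date = "2013-02-07", onset = "23:00", waking = "07:10"))
  rep <- screen_sleep_log(log, bouts)
  expect_equal(rep$deviation_onset_h, 1 / 3, tolerance = 1e-6)
  expect_equal(rep$deviation_waking_h, 5 / 60, tolerance = 1e-6)
  expect_false(rep$flagged)
  expect_equal(rep$suggested_fix, "none")
})

test_that("an AM/PM-confused onset is flagged with the flip suggested", {
  bouts <- tibble::tibble(
    bout_id = 1L,
    start = t_utc("2013-02-07 23:02:00"),
    end = t_utc("2013-02-08 07:05:00"),
    duration_min = 483
  )
  log <- parse_sleep_log(data.frame(date = "2013-02-07", onset = "11:05", waking = "07:10"))
  rep <- screen_sleep_log(log, bouts)
  expect_true(rep$flagged)
  expect_gt(rep$deviation_onset_h, 4)
  expect_equal(rep$suggested_fix, "am_pm_flip_onset")
  # applying the fix resolves the night; re-screening does not flag it again
  fixed <- apply_log_fixes(log, rep)
  expect_true(fixed$fixed)
  expect_equal(fixed$onset, t_utc("2013-02-07 23:05:00"))
  rep2 <- screen_sleep_log(fixed, bouts)
  expect_false(rep2$flagged)
})

test_that("swapped onset and waking are recognised", {
  bouts <- tibble::tibble(
    bout_id = 1L,
    start = t_utc("2013-02-07 23:10:00"),
    end = t_utc("2013-02-08 07:05:00"),
    duration_min = 475
  )
  log <- parse_sleep_log(data.frame(date = "2013-02-07", onset = "07:10", waking = "23:15"))
  rep <- screen_sleep_log(log, bouts)
  expect_true(rep$flagged)
  expect_equal(rep$suggested_fix, "swap_onset_waking")
  fixed <- apply_log_fixes(log, rep)
  rep2 <- screen_sleep_log(fixed, bouts)
  expect_false(rep2$flagged)
  expect_lte(rep2$deviation_onset_h, 0.09)
  expect_lte(rep2$deviation_waking_h, 0.09)
})

test_that("screening is idempotent on unflagged nights and handles no bouts", {
  log <- parse_sleep_log(data.frame(date = "2013-02-07", onset = "23:00", waking = "07:10"))
  none <- tibble::tibble(bout_id = integer(), start = t_utc(character()),
                         end = t_utc(character()), duration_min = double())
  rep <- screen_sleep_log(log, none)
  expect_true(rep$flagged)
  expect_equal(rep$deviation_onset_h, Inf)
  expect_equal(rep$suggested_fix, "exclude_ambiguous")

  bouts <- tibble::tibble(bout_id = 1L, start = t_utc("2013-02-07 23:05:00"),
                          end = t_utc("2013-02-08 07:00:00"), duration_min = 475)
  rep1 <- screen_sleep_log(log, bouts)
  fixed <- apply_log_fixes(log, rep1)
  expect_false(fixed$fixed[1]) # nothing to fix
  expect_equal(fixed$onset, log$onset)
  expect_equal(screen_sleep_log(fixed, bouts)$flagged, rep1$flagged)
})

test_that("nights with no qualifying fix are excluded as ambiguous", {
  # reported times 6 h away from any bout in every transformed variant
  bouts <- tibble::tibble(bout_id = 1L, start = t_utc("2013-02-07 23:00:00"),
                          end = t_utc("2013-02-08 07:00:00"), duration_min = 480)
  log <- parse_sleep_log(data.frame(date = "2013-02-07", onset = "16:00", waking = "16:30"))
  rep <- screen_sleep_log(log, bouts)
  expect_true(rep$flagged)
  expect_equal(rep$suggested_fix, "exclude_ambiguous")
  fixed <- apply_log_fixes(log, rep)
  expect_true(fixed$ambiguous)
})

test_that("injected log errors are flagged at the injected rate", {
  cfg <- simulation_config(n_nights = 1, sample_rate_hz = 10, seed = 31,
                           log_am_pm_flip_p = 0.5, log_jitter_sd_min = 5)
  flagged <- injected <- logical(0)
  for (s in 1:20) {
    cfg$seed <- 300 + s
    sim <- simulate_recording(cfg)
    bouts <- detect_bouts(compute_angle_series(sim$recording))
    slog <- simulate_sleep_log(sim$truth, cfg)
    rep <- screen_sleep_log(parse_sleep_log(slog[, 1:3]), bouts)
    flagged <- c(flagged, rep$flagged)
    injected <- c(injected, slog$error_am_pm)
  }
  expect_equal(flagged, injected) # 12-h displacements and only those are caught
})
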