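lights <- t_utc("2013-02-07 23:00:00")

mk_hyp <- function(stages, lights_out = lights) {
  hypnogram(stages, lights_out = lights_out,
            wake_up = lights_out + length(stages) * 30)
}

one_bout <- function(start, end) {
  tibble::tibble(bout_id = 1L, start = t_utc(start), end = t_utc(end),
                 duration_min = as.numeric(difftime(t_utc(end), t_utc(start), units = "mins")))
}

test_that("a bout covering the whole sleep period gives all true positives", {
  hyp <- mk_hyp(rep("N2", 120)) # 1 h, all sleep
  bouts <- one_bout("2013-02-07 22:30:00", "2013-02-08 00:30:00")
  paired <- epoch_classification(bouts, hyp)
  expect_equal(nrow(paired), 120L)
  expect_true(all(paired$truth_sleep & paired$pred_sleep))
  m <- classification_metrics(paired)
  expect_equal(m$accuracy_pct, 100)
  expect_equal(m$sensitivity_pct, 100)
  expect_true(is.na(m$specificity_pct)) # no truth-wake epochs
  expect_true(m$degenerate)
  expect_equal(m$bias_min, 0)
})

test_that("no bouts means zero sensitivity; all-sleep truth flags specificity", {
  hyp <- mk_hyp(rep(c("N1", "N2", "N3", "REM"), 30))
  none <- one_bout("2013-02-07 23:00:00", "2013-02-07 23:00:05")[0, ]
  paired <- epoch_classification(none, hyp)
  m <- classification_metrics(paired)
  expect_equal(m$sensitivity_pct, 0)
  expect_true(is.na(m$specificity_pct))
  expect_equal(m$bias_min, -60) # underestimates by the whole hour
})

test_that("confusion counts match an epoch-by-epoch interval oracle", {
  stages <- rep("N2", 120)
  stages[41:60] <- "W" # 10-min wake block
  hyp <- mk_hyp(stages)
  bouts <- one_bout("2013-02-07 23:15:00", "2013-02-08 00:00:00")
  paired <- epoch_classification(bouts, hyp)

  # oracle: per 30-s epoch, count 5-s sub-epochs whose midpoints fall in the
  # bout; predict sleep at >= 4 of 6
  oracle <- vapply(seq_len(120), function(i) {
    es <- as.numeric(lights) + (i - 1) * 30
    mids <- es + (0:5) * 5 + 2.5
    sum(mids >= as.numeric(bouts$start) & mids < as.numeric(bouts$end)) >= 4
  }, logical(1))
  expect_equal(paired$pred_sleep, oracle)
  expect_equal(paired$truth_sleep, stages != "W")

  m <- classification_metrics(paired)
  tp <- sum(oracle & stages != "W"); fp <- sum(oracle & stages == "W")
  fn <- sum(!oracle & stages != "W"); tn <- sum(!oracle & stages == "W")
  expect_equal(m$sensitivity_pct, 100 * tp / (tp + fn))
  expect_equal(m$specificity_pct, 100 * tn / (tn + fp))
  expect_equal(m$accuracy_pct, 100 * (tp + tn) / 120)
  expect_equal(m$bias_min, ((tp + fp) - (tp + fn)) * 0.5)
})

test_that("an always-sleep prediction forces the degenerate margins", {
  stages <- rep("N2", 120)
  stages[1:24] <- "W" # 12 min wake
  hyp <- mk_hyp(stages)
  bouts <- one_bout("2013-02-07 22:00:00", "2013-02-08 01:00:00")
  m <- classification_metrics(epoch_classification(bouts, hyp))
  expect_equal(m$sensitivity_pct, 100)
  expect_equal(m$specificity_pct, 0)
  expect_equal(m$bias_min, 12)
})

test_that("the 5-s grid expansion agrees with the majority rule on aligned bouts", {
  stages <- rep(c("N2", "W"), each = 60)
  hyp <- mk_hyp(stages)
  bouts <- one_bout("2013-02-07 23:00:00", "2013-02-07 23:30:00")
  maj <- epoch_classification(bouts, hyp, grid = "30s")
  fine <- epoch_classification(bouts, hyp, grid = "5s")
  expect_equal(nrow(fine), 6 * nrow(maj))
  agg <- tapply(fine$pred_sleep, rep(seq_len(nrow(maj)), each = 6), sum) >= 4
  expect_equal(unname(as.vector(agg)), maj$pred_sleep)
})

test_that("evaluation is restricted to the total sleep period", {
  stages <- rep("N2", 120)
  hyp <- hypnogram(stages, lights_out = lights + 600,
                   wake_up = lights + 600 + 40 * 30)
  # stage rows before lights_out are dropped
  paired <- epoch_classification(one_bout("2013-02-07 23:00:00", "2013-02-08 01:00:00"), hyp)
  expect_true(all(paired$epoch_start >= lights + 600))
  expect_lte(nrow(paired), 40L)
  bad <- hypnogram(tibble::tibble(epoch_start = lights + 30 * (0:119), stage = stages),
                   lights_out = lights + 86400, wake_up = lights + 90000)
  expect_error(epoch_classification(one_bout("2013-02-07 23:00:00", "2013-02-08 01:00:00"), bad),
               "overlap")
})

test_that("metrics summarise across patients as mean and SD", {
  hyp <- mk_hyp(rep(c("N2", "N2", "N2", "W"), 30))
  b1 <- one_bout("2013-02-07 23:00:00", "2013-02-08 00:00:00")
  b2 <- one_bout("2013-02-07 23:00:00", "2013-02-07 23:30:00")
  p1 <- epoch_classification(b1, hyp); p1$patient <- "a"
  p2 <- epoch_classification(b2, hyp); p2$patient <- "b"
  both <- dplyr::bind_rows(p1, p2)
  attr(both, "epoch_s") <- 30
  m <- classification_metrics(both)
  expect_equal(nrow(m), 2L)
  s <- metrics_summary(m)
  expect_equal(s$mean[s$metric == "sensitivity_pct"], mean(m$sensitivity_pct))
  expect_equal(s$sd[s$metric == "bias_min"], sd(m$bias_min))
  expect_equal(unique(s$n_patients), 2L)
})

test_that("the parameter grid is monotone and deterministic", {
  p <- sim_patient(seed = 11, wake_p = 0.05)
  grid <- parameter_sweep(p$angles, p$hyp, windows = c(3, 5, 7, 10, 15),
                          angles = c(3, 5, 10))
  expect_equal(nrow(grid), 15L)
  wide <- tidyr::pivot_wider(grid[, c("window_min", "angle_deg", "pred_sleep_epochs")],
                             names_from = "angle_deg", values_from = "pred_sleep_epochs")
  # non-increasing in window length at each fixed angle
  for (col in c("3", "5", "10")) expect_true(all(diff(wide[[col]]) <= 0))
  # non-decreasing in angle threshold at each fixed window
  for (i in seq_len(nrow(wide))) {
    expect_true(wide$`3`[i] <= wide$`5`[i] && wide$`5`[i] <= wide$`10`[i])
  }
  # bias falls down each fixed-angle column
  for (a in c(3, 5, 10)) {
    expect_true(all(diff(grid$bias_min[grid$angle_deg == a]) <= 1e-9))
  }
  grid2 <- parameter_sweep(p$angles, p$hyp, windows = c(3, 5, 7, 10, 15),
                           angles = c(3, 5, 10))
  expect_identical(grid, grid2)
})

test_that("hypnograms round-trip through CSV with their JSON sidecar", {
  p <- sim_patient(seed = 12)
  dir <- withr::local_tempdir()
  hyp <- p$hyp
  readr::write_csv(tibble::as_tibble(hyp), file.path(dir, "h.csv"))
  jsonlite::write_json(
    list(lights_out = format(attr(hyp, "lights_out"), "%Y-%m-%dT%H:%M:%S"),
         wake_up = format(attr(hyp, "wake_up"), "%Y-%m-%dT%H:%M:%S"),
         epoch_s = 30),
    file.path(dir, "h.json"), auto_unbox = TRUE
  )
  h2 <- read_hypnogram(file.path(dir, "h.csv"))
  expect_equal(h2$stage, hyp$stage)
  expect_equal(as.numeric(attr(h2, "lights_out")),
               as.numeric(attr(hyp, "lights_out")), tolerance = 1)
  expect_error(hypnogram(c("N2", "Q"), lights, lights + 60), "unknown")
})
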