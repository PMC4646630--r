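#' Simulation configuration
#'
#' Parameters of the synthetic multi-night accelerometer generator. The
#' generator emulates the signal structure the detector relies on: a
#' piecewise-constant gravity orientation with frequent posture changes while
#' awake (exponential dwell with mean `wake_posture_dwell_s`, capped at
#' `wake_dwell_max_s` so that waking stillness never reaches the minimum
#' bout duration), rare position shifts while asleep (dwell of at least
#' `sleep_dwell_min_min` minutes plus an exponential excess, mean
#' `sleep_posture_dwell_min`), additive Gaussian sensor noise, and known
#' ground-truth sleep windows drawn from a nightly schedule. Orientation
#' changes move the arm angle by at least `movement_min_deg` (above the
#' detector threshold, so wake is detectable by construction) and at most
#' `movement_max_deg`.
#'
#' @param n_nights Number of simulated noon-to-noon days.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param start_date Calendar date of the first day (a Monday by default).
#' @param onset_mean,wake_mean Mean sleep onset / waking clock times
#'   (`"HH:MM"`).
#' @param onset_sd_min,wake_sd_min Night-to-night SD of the schedule, minutes.
#' @param wake_posture_dwell_s Mean seconds between orientation changes while
#'   awake.
#' @param wake_dwell_max_s Upper cap on a waking dwell, seconds.
#' @param sleep_posture_dwell_min Mean minutes between position shifts while
#'   asleep.
#' @param sleep_dwell_min_min Minimum sleeping dwell, minutes.
#' @param movement_min_deg,movement_max_deg Arm-angle step size range of a
#'   posture change, degrees.
#' @param noise_sd_g Sensor noise SD per axis, g.
#' @param log_am_pm_flip_p Probability that a night's reported onset is
#'   entered 12 h off (AM/PM confusion).
#' @param log_swap_p Probability that reported onset and waking are swapped.
#' @param log_jitter_sd_min SD of the reporting jitter, minutes.
#' @param move_on_transition Force a posture change at every sleep/wake
#'   transition (falling asleep and waking up are movements). Disable only
#'   for degenerate test signals.
#' @param nap_rate Expected daytime naps per day (Poisson).
#' @param nap_min_min,nap_max_min Nap duration range, minutes.
#' @param psg_wake_block_p Probability per 30-s epoch of starting an inserted
#'   wake block in a simulated hypnogram.
#' @param psg_wake_block_max_epochs Maximum inserted wake-block length,
#'   epochs.
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_nights = 1,
                              sample_rate_hz = 50,
                              start_date = as.Date("2013-02-04"),
                              onset_mean = "23:15", onset_sd_min = 15,
                              wake_mean = "06:15", wake_sd_min = 15,
                              wake_posture_dwell_s = 60,
                              wake_dwell_max_s = 240,
                              sleep_posture_dwell_min = 20,
                              sleep_dwell_min_min = 15,
                              movement_min_deg = 10,
                              movement_max_deg = 60,
                              noise_sd_g = 0.01,
                              log_am_pm_flip_p = 0,
                              log_swap_p = 0,
                              log_jitter_sd_min = 10,
                              move_on_transition = TRUE,
                              nap_rate = 0,
                              nap_min_min = 20, nap_max_min = 60,
                              psg_wake_block_p = 0.02,
                              psg_wake_block_max_epochs = 6,
                              seed = 1L) {
  cfg <- as.list(environment())
  for (p in c("log_am_pm_flip_p", "log_swap_p", "psg_wake_block_p")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) abort(sprintf("`%s` must be in [0, 1]", p))
  }
  for (p in c("n_nights", "sample_rate_hz", "wake_posture_dwell_s",
              "sleep_posture_dwell_min", "movement_min_deg")) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0) abort(sprintf("`%s` must be positive", p))
  }
  if (cfg$wake_posture_dwell_s < 1 / cfg$sample_rate_hz) {
    abort("waking dwell time is shorter than the sampling interval")
  }
  if (cfg$sleep_dwell_min_min > cfg$sleep_posture_dwell_min) {
    abort("`sleep_dwell_min_min` cannot exceed the mean sleeping dwell")
  }
  if (cfg$movement_max_deg <= cfg$movement_min_deg) {
    abort("`movement_max_deg` must exceed `movement_min_deg`")
  }
  structure(cfg, class = "simulation_config")
}

clock_to_sec <- function(x) {
  m <- parse_clock_min(x)
  if (is.na(m)) abort(sprintf("cannot parse clock time '%s'", x))
  m * 60
}

# New arm angle at a posture change: step of size in [min, max] degrees in a
# random direction, reflected back into [-90, 90]; redrawn if the reflection
# lands closer than the minimum step.
draw_angle_step <- function(old, min_deg, max_deg) {
  for (i in 1:100) {
    cand <- old + sample(c(-1, 1), 1) * runif(1, min_deg, max_deg)
    if (cand > 90) cand <- 180 - cand
    if (cand < -90) cand <- -180 - cand
    if (abs(cand - old) >= min_deg) return(cand)
  }
  -old # fallback; |old| >= 5 whenever the retry loop can stall
}

in_any_interval <- function(t, ints) {
  if (nrow(ints) == 0L) return(FALSE)
  any(t >= ints$start & t < ints$end)
}

#' Simulate a raw multi-night recording with known ground truth
#'
#' Generates `n_nights` consecutive noon-to-noon days of tri-axial
#' acceleration at `sample_rate_hz`: a unit-norm gravity vector whose
#' orientation is piecewise constant between posture changes (fast dwell
#' while awake, slow while asleep), plus Gaussian noise. Deterministic under
#' the configuration seed.
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `sim_sleep` with elements `recording` (tibble
#'   `timestamp, x, y, z`), `truth` (list with `nights` — tibble
#'   `night, night_date, onset, waking` — and `naps`), and `config`.
#' @export
simulate_recording <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::local_seed(cfg$seed)

  t0 <- as.POSIXct(paste(cfg$start_date, "12:00:00"), tz = "UTC")
  total_s <- cfg$n_nights * 86400
  fs <- cfg$sample_rate_hz

  onset_base <- clock_to_sec(cfg$onset_mean)   # seconds after each day's midnight
  wake_base <- clock_to_sec(cfg$wake_mean)

  nights <- purrr::map_dfr(seq_len(cfg$n_nights), function(i) {
    day0 <- as.POSIXct(paste(cfg$start_date + (i - 1L), "00:00:00"), tz = "UTC")
    tibble::tibble(
      night = i,
      night_date = cfg$start_date + (i - 1L),
      onset = day0 + onset_base + rnorm(1, 0, cfg$onset_sd_min * 60),
      waking = day0 + 86400 + wake_base + rnorm(1, 0, cfg$wake_sd_min * 60)
    )
  })

  naps <- tibble::tibble(start = t0[0], end = t0[0])
  if (cfg$nap_rate > 0) {
    naps <- purrr::map_dfr(seq_len(cfg$n_nights), function(i) {
      k <- stats::rpois(1, cfg$nap_rate)
      if (k == 0L) return(tibble::tibble(start = t0[0], end = t0[0]))
      day0 <- as.POSIXct(paste(cfg$start_date + (i - 1L), "00:00:00"), tz = "UTC")
      st <- day0 + runif(k, 13 * 3600, 17 * 3600)
      tibble::tibble(start = st,
                     end = st + runif(k, cfg$nap_min_min * 60, cfg$nap_max_min * 60))
    })
  }

  sleep_ints <- dplyr::bind_rows(
    tibble::tibble(start = nights$onset, end = nights$waking),
    naps
  )

  # Posture-change walk over the whole timeline. Dwells are truncated at
  # sleep/wake (and nap) boundaries: falling asleep and waking up are
  # movements, so a posture change is forced at each transition.
  t_end <- as.numeric(t0) + total_s
  boundaries <- if (isTRUE(cfg$move_on_transition)) {
    sort(unique(as.numeric(c(sleep_ints$start, sleep_ints$end))))
  } else {
    numeric(0)
  }
  times <- as.numeric(t0)
  angles <- runif(1, -60, 60)
  phis <- runif(1, 0, 2 * pi)
  t <- as.numeric(t0)
  repeat {
    asleep <- in_any_interval(t, sleep_ints)
    dwell <- if (asleep) {
      cfg$sleep_dwell_min_min * 60 +
        rexp(1, 1 / ((cfg$sleep_posture_dwell_min - cfg$sleep_dwell_min_min) * 60 + 1e-9))
    } else {
      min(rexp(1, 1 / cfg$wake_posture_dwell_s), cfg$wake_dwell_max_s)
    }
    nb <- boundaries[boundaries > t]
    t <- if (length(nb)) min(t + dwell, nb[1]) else t + dwell
    if (t >= t_end) break
    times <- c(times, t)
    angles <- c(angles, draw_angle_step(angles[length(angles)],
                                        cfg$movement_min_deg, cfg$movement_max_deg))
    phis <- c(phis, runif(1, 0, 2 * pi))
  }

  # expand segment orientations to samples via run lengths
  n <- floor(total_s * fs)
  first_idx <- pmin(ceiling((times - as.numeric(t0)) * fs) + 1, n + 1)
  first_idx[1] <- 1
  lens <- diff(c(first_idx, n + 1))
  th <- angles * pi / 180
  gx <- rep.int(cos(th) * cos(phis), lens)
  gy <- rep.int(cos(th) * sin(phis), lens)
  gz <- rep.int(sin(th), lens)

  recording <- tibble::tibble(
    timestamp = as.POSIXct(as.numeric(t0) + (seq_len(n) - 1) / fs,
                           tz = "UTC", origin = "1970-01-01"),
    x = gx + rnorm(n, 0, cfg$noise_sd_g),
    y = gy + rnorm(n, 0, cfg$noise_sd_g),
    z = gz + rnorm(n, 0, cfg$noise_sd_g)
  )

  structure(
    list(recording = recording,
         truth = list(nights = nights, naps = naps),
         config = cfg),
    class = "sim_sleep"
  )
}

#' Ground-truth sleep labels on an epoch grid
#'
#' @param truth The `truth` element of a [simulate_recording()] result.
#' @param from,to POSIXct span to label.
#' @param epoch_s Epoch length, seconds.
#' @param include_naps Count naps as sleep (default `FALSE`: nocturnal sleep
#'   only).
#' @return A tibble `epoch_start, asleep` labelling each epoch by its
#'   midpoint.
#' @export
truth_epoch_labels <- function(truth, from, to, epoch_s = 5,
                               include_naps = FALSE) {
  starts <- seq(from, to - epoch_s, by = epoch_s)
  mid <- as.numeric(starts) + epoch_s / 2
  ints <- tibble::tibble(start = truth$nights$onset, end = truth$nights$waking)
  if (include_naps) ints <- dplyr::bind_rows(ints, truth$naps)
  asleep <- rep(FALSE, length(mid))
  for (i in seq_len(nrow(ints))) {
    asleep <- asleep |
      (mid >= as.numeric(ints$start[i]) & mid < as.numeric(ints$end[i]))
  }
  tibble::tibble(epoch_start = starts, asleep = asleep)
}

#' Simulate a sleep log from ground truth
#'
#' Reported times are the true onset/waking plus Gaussian jitter; with
#' probability `log_am_pm_flip_p` the reported onset is shifted 12 h (AM/PM
#' confusion) and with probability `log_swap_p` onset and waking are swapped.
#' Error bookkeeping is retained so screening can be evaluated against the
#' injected errors.
#'
#' @param truth The `truth` element of a [simulate_recording()] result.
#' @param cfg The matching [simulation_config()].
#' @return A tibble with the sleep-log columns `date, onset, waking`
#'   (`HH:MM` strings, ready for [parse_sleep_log()]) plus bookkeeping
#'   columns `error_am_pm`, `error_swap`, `true_onset`, `true_waking`.
#' @export
simulate_sleep_log <- function(truth, cfg) {
  withr::local_seed(cfg$seed + 1000L)
  nights <- truth$nights
  n <- nrow(nights)
  jit <- cfg$log_jitter_sd_min * 60
  onset_rep <- nights$onset + rnorm(n, 0, jit)
  waking_rep <- nights$waking + rnorm(n, 0, jit)

  oc <- (lubridate::hour(onset_rep) * 60 + lubridate::minute(onset_rep))
  wc <- (lubridate::hour(waking_rep) * 60 + lubridate::minute(waking_rep))

  flip <- rbinom(n, 1, cfg$log_am_pm_flip_p) == 1L
  swap <- rbinom(n, 1, cfg$log_swap_p) == 1L
  oc[flip] <- (oc[flip] + 720) %% 1440
  tmp <- oc[swap]; oc[swap] <- wc[swap]; wc[swap] <- tmp

  tibble::tibble(
    date = nights$night_date,
    onset = format_clock(oc),
    waking = format_clock(wc),
    error_am_pm = flip,
    error_swap = swap,
    true_onset = nights$onset,
    true_waking = nights$waking
  )
}

#' Simulate a hypnogram for one night of ground truth
#'
#' Produces a 30-s staged sequence over the night's total sleep period
#' (lights out at the true onset, wake up at the true waking time): a
#' repeating non-REM/REM stage cycle with wake blocks inserted at the
#' configured rate.
#'
#' @param truth The `truth` element of a [simulate_recording()] result.
#' @param cfg The matching [simulation_config()].
#' @param night Which night to stage (default 1).
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(truth, cfg, night = 1) {
  withr::local_seed(cfg$seed + 2000L + as.integer(night))
  row <- truth$nights[truth$nights$night == night, ]
  if (nrow(row) != 1L) abort("no such night in the ground truth")
  lights_out <- row$onset
  wake_up <- row$waking
  n_ep <- floor(as.numeric(difftime(wake_up, lights_out, units = "secs")) / 30)

  cycle <- rep(c("N1", "N2", "N3", "N3", "N2", "REM"), each = 30) # ~90-min cycle
  stages <- rep_len(cycle, n_ep)

  i <- 1L
  while (i <= n_ep) {
    if (runif(1) < cfg$psg_wake_block_p) {
      len <- sample.int(cfg$psg_wake_block_max_epochs, 1)
      stages[i:min(n_ep, i + len - 1L)] <- "W"
      i <- i + len
    }
    i <- i + 1L
  }

  hypnogram(stages, lights_out = lights_out, wake_up = wake_up, epoch_s = 30)
}

#' Write simulated fixtures to a directory
#'
#' Emits the raw recording CSV, sleep-log CSV, first-night hypnogram CSV with
#' its JSON sidecar, and a ground-truth JSON under `dir`.
#'
#' @param sim A [simulate_recording()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(x) format(x, "%Y-%m-%dT%H:%M:%OS2")
  p_raw <- file.path(dir, "raw.csv")
  rec <- dplyr::mutate(sim$recording, timestamp = fmt(.data$timestamp))
  readr::write_csv(rec, p_raw, progress = FALSE)

  p_log <- file.path(dir, "sleep_log.csv")
  log <- simulate_sleep_log(sim$truth, sim$config)
  readr::write_csv(log[, c("date", "onset", "waking")], p_log, progress = FALSE)

  hyp <- simulate_hypnogram(sim$truth, sim$config)
  p_hyp <- file.path(dir, "hypnogram.csv")
  readr::write_csv(
    dplyr::mutate(tibble::as_tibble(hyp), epoch_start = fmt(.data$epoch_start)),
    p_hyp, progress = FALSE
  )
  p_meta <- file.path(dir, "hypnogram.json")
  jsonlite::write_json(
    list(lights_out = fmt(attr(hyp, "lights_out")),
         wake_up = fmt(attr(hyp, "wake_up")),
         epoch_s = attr(hyp, "epoch_s")),
    p_meta, auto_unbox = TRUE
  )

  p_truth <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(nights = dplyr::mutate(sim$truth$nights,
                                onset = fmt(.data$onset),
                                waking = fmt(.data$waking)),
         naps = dplyr::mutate(sim$truth$naps,
                              start = fmt(.data$start),
                              end = fmt(.data$end))),
    p_truth, auto_unbox = TRUE
  )
  invisible(c(p_raw, p_log, p_hyp, p_meta, p_truth))
}
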