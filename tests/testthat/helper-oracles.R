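# Shared fixtures and independent oracles, all built in code.

t_utc <- function(x) as.POSIXct(x, tz = "UTC")

# Angle series tibble on a 5-s grid (or other epoch length).
make_series <- function(angle_deg, start = t_utc("2013-02-07 23:00:00"),
                        epoch_s = 5) {
  out <- tibble::tibble(
    epoch_start = start + (seq_along(angle_deg) - 1L) * epoch_s,
    angle_deg = angle_deg
  )
  attr(out, "epoch_s") <- epoch_s
  out
}

# Constant-orientation raw recording.
make_raw <- function(x, y, z, secs, fs = 10,
                     start = t_utc("2013-02-07 12:00:00"), wear = NULL) {
  n <- secs * fs
  out <- tibble::tibble(
    timestamp = start + (seq_len(n) - 1) / fs,
    x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n)
  )
  if (!is.null(wear)) out$wear <- rep_len(wear, n)
  out
}

# Brute-force maximal-run scan: walk the series position by position,
# extending each run while the adjacent difference stays within the
# threshold, and keep runs meeting the minimum span. Independent of the
# vectorized implementation in detect_bouts().
brute_bouts <- function(series, config) {
  ang <- series$angle_deg
  epoch_s <- attr(series, "epoch_s")
  n <- length(ang)
  res <- list()
  i <- 1L
  while (i <= n) {
    if (is.na(ang[i])) { i <- i + 1L; next }
    j <- i
    while (j < n && !is.na(ang[j + 1L]) &&
           abs(ang[j + 1L] - ang[j]) <= config$angle_threshold_deg) {
      j <- j + 1L
    }
    if ((j - i + 1L) * epoch_s >= config$min_bout_min * 60) {
      res[[length(res) + 1L]] <- data.frame(
        start = series$epoch_start[i],
        end = series$epoch_start[j] + epoch_s,
        duration_min = (j - i + 1L) * epoch_s / 60
      )
    }
    i <- j + 1L
  }
  if (!length(res)) {
    return(tibble::tibble(bout_id = integer(), start = series$epoch_start[0],
                          end = series$epoch_start[0], duration_min = double()))
  }
  out <- dplyr::bind_rows(res)
  tibble::tibble(bout_id = seq_len(nrow(out)), start = out$start,
                 end = out$end, duration_min = out$duration_min)
}

# Random epoch series mixing slow drift, abrupt posture changes and missing
# stretches — the regimes the detector has to segment.
random_series <- function(n) {
  steps <- rnorm(n, 0, 2)
  jumps <- runif(n) < 0.03
  steps[jumps] <- sample(c(-1, 1), sum(jumps), replace = TRUE) * runif(sum(jumps), 6, 40)
  ang <- pmax(-90, pmin(90, cumsum(steps)))
  if (runif(1) < 0.3) {
    gap <- sample(n, 1)
    ang[gap:min(n, gap + sample(0:20, 1))] <- NA
  }
  make_series(ang)
}

# Interval containment: is every [start, end] of `a` inside some bout of `b`?
bouts_contained_in <- function(a, b) {
  all(vapply(seq_len(nrow(a)), function(i) {
    any(b$start <= a$start[i] & b$end >= a$end[i])
  }, logical(1)))
}

# Small simulated patient shared by PSG tests: low rate keeps it fast while
# leaving the detector's behaviour unchanged.
sim_patient <- function(seed = 11, wake_p = 0.05) {
  cfg <- simulation_config(n_nights = 1, sample_rate_hz = 10, seed = seed,
                           psg_wake_block_p = wake_p)
  sim <- simulate_recording(cfg)
  list(cfg = cfg, sim = sim,
       angles = compute_angle_series(sim$recording),
       hyp = simulate_hypnogram(sim$truth, cfg))
}
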