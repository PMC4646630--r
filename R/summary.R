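#' Select nocturnal bouts
#'
#' A sustained-inactivity bout is considered nocturnal sleep when it overlaps
#' the sleep window reported in the log (non-empty intersection with
#' `[onset, waking]`); this separates sleep from daytime naps and quiet
#' wakefulness. Overlapping bouts are kept at full extent by default — the
#' night's onset/waking definitions refer to bout starts and ends, not
#' clipped times — with `clip_to_log = TRUE` as the alternative.
#'
#' @param bouts Bout tibble ([detect_bouts()]).
#' @param onset,waking Reported sleep period (POSIXct scalars).
#' @param clip_to_log Clip bout extents to the reported window.
#' @return The subset of `bouts` overlapping the reported window.
#' @export
classify_nocturnal <- function(bouts, onset, waking, clip_to_log = FALSE) {
  if (is.na(onset) || is.na(waking)) return(bouts[0, ])
  noct <- bouts[bouts$start < waking & bouts$end > onset, ]
  if (clip_to_log && nrow(noct)) {
    noct$start <- pmax(noct$start, onset)
    noct$end <- pmin(noct$end, waking)
    noct$duration_min <- as.numeric(difftime(noct$end, noct$start, units = "mins"))
  }
  noct
}

exclusion_levels <- c(
  "none", "first_night", "ninth_night", "wear_lt_16h",
  "log_missing", "log_ambiguous", "no_sleep_detected"
)

#' Per-night sleep summaries
#'
#' Combines detected bouts with the sleep log into one row per night over its
#' 24-h analysis window. Bouts are assigned to the window containing their
#' midpoint; bouts overlapping the reported sleep period are nocturnal sleep.
#' Derived variables: *sleep onset* (start of the first nocturnal bout),
#' *waking time* (end of the last nocturnal bout), *time in bed* (waking
#' minus onset) and *total sleep duration* (sum of nocturnal bout durations).
#'
#' Validity rules, applied in order of precedence: the first and (if present)
#' ninth night of the recording protocol are excluded; nights with less than
#' 16 h of detected wear time are excluded; nights with a missing or
#' ambiguous log entry are excluded; nights with no nocturnal bout carry
#' undefined durations.
#'
#' @param bouts Bout tibble ([detect_bouts()]).
#' @param log Parsed sleep log; windows are assigned with
#'   [assign_night_window()] if not already present.
#' @param wear Optional tibble `night_date, wear_h` with detected wear hours
#'   per 24-h window; nights absent from it (or `wear = NULL`) are assumed
#'   fully worn (24 h).
#' @param exclude_protocol_nights Apply the first/ninth-night exclusion
#'   (default `TRUE`; disable for free-standing simulated nights).
#' @param clip_to_log See [classify_nocturnal()].
#' @param min_wear_h Minimum wear time per night in hours (default 16).
#' @return A tibble with one row per night: `night_date`, `night_index`,
#'   `window_start`, `window_end`, `window_kind`, `sleep_onset`,
#'   `waking_time`, `time_in_bed_h`, `total_sleep_h`, `n_nocturnal_bouts`,
#'   `wear_h`, `valid`, `exclusion_reason`.
#' @export
summarize_nights <- function(bouts, log, wear = NULL,
                             exclude_protocol_nights = TRUE,
                             clip_to_log = FALSE, min_wear_h = 16) {
  if (!"window_start" %in% names(log)) log <- assign_night_window(log)

  all_dates <- seq(min(log$night_date), max(log$night_date), by = "day")
  night_index <- as.integer(all_dates - min(all_dates)) + 1L

  rows <- purrr::map2(all_dates, night_index, function(nd, idx) {
    entry <- log[log$night_date == nd, ]
    has_entry <- nrow(entry) == 1L
    if (has_entry) {
      ws <- entry$window_start; we <- entry$window_end; kind <- entry$window_kind
    } else {
      ws <- as.POSIXct(paste(nd, "12:00:00"), tz = "UTC"); we <- ws + 86400
      kind <- "standard"
    }

    wear_h <- 24
    if (!is.null(wear)) {
      w <- wear$wear_h[wear$night_date == nd]
      if (length(w) == 1L) wear_h <- w
    }

    mid <- bouts$start + (bouts$end - bouts$start) / 2
    in_win <- bouts[mid >= ws & mid < we, ]
    noct <- if (has_entry && !entry$ambiguous) {
      classify_nocturnal(in_win, entry$onset, entry$waking, clip_to_log)
    } else {
      in_win[0, ]
    }

    reason <- "none"
    if (exclude_protocol_nights && idx == 1L) reason <- "first_night"
    else if (exclude_protocol_nights && idx == 9L) reason <- "ninth_night"
    else if (wear_h < min_wear_h) reason <- "wear_lt_16h"
    else if (!has_entry) reason <- "log_missing"
    else if (entry$ambiguous) reason <- "log_ambiguous"
    else if (nrow(noct) == 0L) reason <- "no_sleep_detected"

    has_sleep <- nrow(noct) > 0L
    onset_t <- if (has_sleep) min(noct$start) else as.POSIXct(NA, tz = "UTC")
    waking_t <- if (has_sleep) max(noct$end) else as.POSIXct(NA, tz = "UTC")

    tibble::tibble(
      night_date = nd,
      night_index = idx,
      window_start = ws,
      window_end = we,
      window_kind = kind,
      sleep_onset = onset_t,
      waking_time = waking_t,
      time_in_bed_h = as.numeric(difftime(waking_t, onset_t, units = "hours")),
      total_sleep_h = if (has_sleep) sum(noct$duration_min) / 60 else NA_real_,
      n_nocturnal_bouts = nrow(noct),
      wear_h = wear_h,
      valid = reason == "none",
      exclusion_reason = reason
    )
  })
  dplyr::bind_rows(rows)
}

#' Weekly weighted sleep averages
#'
#' Averages valid nights separately over weekdays (Sunday-Thursday nights)
#' and weekend days (Friday and Saturday nights), labelling each night by the
#' weekday of its window start, and combines them as
#' `(weekday mean * 5 + weekend mean * 2) / 7`. A participant is eligible
#' only with at least one valid weekday and one valid weekend night.
#'
#' @param nights Night summaries from [summarize_nights()].
#' @return A tibble with one row per variable (`time_in_bed_h`,
#'   `total_sleep_h`): `weekday_mean`, `weekend_mean`, `weekly_weighted_mean`
#'   (hours), `n_weekday_nights`, `n_weekend_nights`, `eligible`.
#' @export
weekly_summary <- function(nights) {
  valid <- nights[nights$valid & !is.na(nights$total_sleep_h), ]
  wd <- lubridate::wday(valid$window_start, week_start = 1) # 1 = Mon ... 7 = Sun
  is_weekend <- wd %in% c(5L, 6L) # Friday, Saturday nights
  purrr::map_dfr(c("time_in_bed_h", "total_sleep_h"), function(v) {
    wk <- valid[[v]][!is_weekend]
    we <- valid[[v]][is_weekend]
    wk_m <- if (length(wk)) mean(wk) else NA_real_
    we_m <- if (length(we)) mean(we) else NA_real_
    tibble::tibble(
      variable = v,
      weekday_mean = wk_m,
      weekend_mean = we_m,
      weekly_weighted_mean = (wk_m * 5 + we_m * 2) / 7,
      n_weekday_nights = length(wk),
      n_weekend_nights = length(we),
      eligible = length(wk) >= 1L && length(we) >= 1L
    )
  })
}

duration_levels <- c("<=5", "6", "7", "8", ">=9")

#' Categorize sleep duration
#'
#' Rounds a duration in hours to the nearest integer (ties round half-up) and
#' maps it onto the 5-level ordinal scale used for agreement analyses:
#' `<=5`, `6`, `7`, `8`, `>=9` hours.
#'
#' @param hours Non-negative numeric vector of durations in hours.
#' @return An ordered factor with levels `<=5 < 6 < 7 < 8 < >=9`.
#' @examples
#' categorize_duration(c(4.2, 7.5, 7.6, 9.4))
#' @export
categorize_duration <- function(hours) {
  if (any(hours < 0, na.rm = TRUE)) abort("durations must be non-negative")
  rounded <- floor(hours + 0.5) # half-up
  idx <- pmin(pmax(rounded, 5), 9) - 4
  factor(duration_levels[idx], levels = duration_levels, ordered = TRUE)
}
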