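# Clock-time helpers ---------------------------------------------------------

# Parse "HH:MM" (24 h) or "H:MM AM/PM" into minutes since midnight; NA when
# malformed (bad format, hour/minute out of range).
parse_clock_min <- function(x) {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})(?:\\s*([AaPp])[Mm])?$", x))
  vapply(m, function(g) {
    if (length(g) == 0L) return(NA_real_)
    hh <- as.numeric(g[2]); mm <- as.numeric(g[3]); ap <- toupper(g[4])
    if (mm >= 60) return(NA_real_)
    if (nzchar(ap)) {
      if (hh < 1 || hh > 12) return(NA_real_)
      hh <- hh %% 12 + if (ap == "P") 12 else 0
    } else if (hh >= 24) {
      return(NA_real_)
    }
    hh * 60 + mm
  }, numeric(1))
}

format_clock <- function(minutes) {
  sprintf("%02d:%02d", as.integer(minutes) %/% 60L, as.integer(minutes) %% 60L)
}

# Resolve a reported sleep-onset clock time onto the calendar: evening times
# (18:00-23:59) belong to the night's own date, after-midnight times
# (00:00-17:59) to the next date.
resolve_onset <- function(night_date, clock_min) {
  date0 <- as.POSIXct(paste(night_date, "00:00:00"), tz = "UTC")
  date0 + ifelse(clock_min >= 18 * 60, clock_min * 60, clock_min * 60 + 86400)
}

# Resolve a reported waking clock time to the first occurrence strictly after
# sleep onset (guarantees waking > onset).
resolve_waking <- function(onset, clock_min) {
  day0 <- lubridate::floor_date(onset, "day")
  w <- day0 + clock_min * 60
  w + ifelse(w > onset, 0, 86400)
}

# Sleep-log parsing -----------------------------------------------------------

#' Parse a sleep log
#'
#' Reads per-night sleep-log entries answering "what time did you first fall
#' asleep last night?" and "what time did you wake up today?" and resolves
#' the clock times onto the calendar. Onset times from 18:00-23:59 are placed
#' on the night's own date and times from 00:00-17:59 on the following date;
#' the waking time is the first occurrence of its clock time after the
#' resolved onset. Malformed rows are retained and marked `ambiguous` with a
#' reason, never silently dropped.
#'
#' @param x Path to a CSV with header `date,onset,waking` (times as `HH:MM`
#'   24-hour or `HH:MM AM/PM`), or a data frame with those columns.
#' @return A tibble with columns `night_date` (Date), `onset`, `waking`
#'   (POSIXct or NA), `onset_clock`, `waking_clock` (character),
#'   `ambiguous` (logical) and `reason` (character).
#' @examples
#' log <- parse_sleep_log(data.frame(
#'   date = c("2013-02-07", "2013-02-08"),
#'   onset = c("23:30", "00:45"),
#'   waking = c("07:15", "06:50")
#' ))
#' log$onset # 2013-02-07 23:30, 2013-02-09 00:45 (after-midnight rule)
#' @export
parse_sleep_log <- function(x) {
  df <- if (is.character(x)) {
    readr::read_csv(x, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else {
    x
  }
  miss <- setdiff(c("date", "onset", "waking"), names(df))
  if (length(miss)) abort(paste("sleep log is missing columns:", paste(miss, collapse = ", ")))

  night_date <- as.Date(as.character(df$date))
  if (anyNA(night_date)) abort("unparseable dates in sleep log")
  if (anyDuplicated(night_date)) abort("duplicate nights in sleep log")

  oc <- parse_clock_min(df$onset)
  wc <- parse_clock_min(df$waking)
  ambiguous <- is.na(oc) | is.na(wc)
  reason <- ifelse(ambiguous, "unparseable time", NA_character_)

  onset <- resolve_onset(night_date, oc)
  waking <- resolve_waking(onset, wc)
  onset[ambiguous] <- NA
  waking[ambiguous] <- NA

  tibble::tibble(
    night_date = night_date,
    onset = onset,
    waking = waking,
    onset_clock = ifelse(is.na(oc), as.character(df$onset), format_clock(oc)),
    waking_clock = ifelse(is.na(wc), as.character(df$waking), format_clock(wc)),
    ambiguous = ambiguous,
    reason = reason
  )
}

#' Assign the 24-h analysis window for each night
#'
#' Each night is summarized over a standard noon-to-noon window. When the log
#' marks a day sleeper — onset clock time strictly before noon and waking
#' clock time strictly after noon — a 18:00-to-18:00 window is used instead,
#' so the daytime sleep period is not split across windows. Nights with a
#' missing or ambiguous entry get the standard window and keep their flag.
#'
#' @param log Parsed sleep log from [parse_sleep_log()].
#' @return `log` with added columns `window_start`, `window_end` (POSIXct,
#'   exactly 24 h apart) and `window_kind` (`"standard"` or `"day_sleeper"`).
#' @export
assign_night_window <- function(log) {
  oc <- parse_clock_min(log$onset_clock)
  wc <- parse_clock_min(log$waking_clock)
  day_sleeper <- !is.na(oc) & !is.na(wc) & oc < 12 * 60 & wc > 12 * 60
  start_h <- ifelse(day_sleeper, 18, 12)
  ws <- as.POSIXct(paste(log$night_date, "00:00:00"), tz = "UTC") + start_h * 3600
  dplyr::mutate(
    log,
    window_start = ws,
    window_end = ws + 86400,
    window_kind = ifelse(day_sleeper, "day_sleeper", "standard")
  )
}

# Outlier screening -----------------------------------------------------------

min_dist_h <- function(times, edges) {
  if (length(edges) == 0L) return(rep(Inf, length(times)))
  vapply(as.numeric(times), function(t) {
    if (is.na(t)) NA_real_ else min(abs(t - as.numeric(edges))) / 3600
  }, numeric(1))
}

# All candidate corrections of a log entry: any combination of swapping the
# two clock times and shifting either by 12 h. Labels collapse the
# flip-plus-swap combinations into "flip_and_swap".
fix_grid <- function() {
  g <- expand.grid(swap = c(FALSE, TRUE), flip_onset = c(FALSE, TRUE),
                   flip_waking = c(FALSE, TRUE))
  g$label <- with(g, ifelse(
    !swap & flip_onset & !flip_waking, "am_pm_flip_onset",
    ifelse(!swap & !flip_onset & flip_waking, "am_pm_flip_waking",
    ifelse(!swap & flip_onset & flip_waking, "am_pm_flip_both",
    ifelse(swap & !flip_onset & !flip_waking, "swap_onset_waking",
    ifelse(swap, "flip_and_swap", "none"))))))
  g
}

apply_fix_transform <- function(night_date, onset_clock_min, waking_clock_min,
                                swap, flip_onset, flip_waking) {
  oc <- onset_clock_min; wc <- waking_clock_min
  if (swap) { tmp <- oc; oc <- wc; wc <- tmp }
  if (flip_onset) oc <- (oc + 720) %% 1440
  if (flip_waking) wc <- (wc + 720) %% 1440
  onset <- resolve_onset(night_date, oc)
  list(onset = onset, waking = resolve_waking(onset, wc),
       onset_clock_min = oc, waking_clock_min = wc)
}

#' Screen sleep-log entries against detected bouts
#'
#' Flags nights whose reported sleep onset and/or waking time deviates by more
#' than `threshold_h` hours from the nearest detected sustained-inactivity
#' bout. Onset times are matched to bout starts and waking times to bout ends
#' (log times are point events compared with bout boundaries). For flagged
#' nights every candidate correction — a 12-h shift of either time, swapping
#' onset and waking, and their combinations — is applied hypothetically; the
#' fix bringing both deviations within the threshold (ties broken by smallest
#' total deviation) is suggested, or `exclude_ambiguous` when none qualifies.
#' Nothing is applied automatically; see [apply_log_fixes()].
#'
#' @param log Parsed sleep log ([parse_sleep_log()]).
#' @param bouts Bout tibble ([detect_bouts()]) from the same recording period.
#' @param threshold_h Deviation threshold in hours (default 4).
#' @return A tibble with columns `night_date`, `deviation_onset_h`,
#'   `deviation_waking_h`, `flagged` and `suggested_fix` (`"none"`,
#'   `"am_pm_flip_onset"`, `"am_pm_flip_waking"`, `"am_pm_flip_both"`,
#'   `"swap_onset_waking"`, `"flip_and_swap"`, `"exclude_ambiguous"`).
#'   Unparseable log rows are reported flagged with `NA` deviations and
#'   `exclude_ambiguous`.
#' @export
screen_sleep_log <- function(log, bouts, threshold_h = 4) {
  if (!is.numeric(threshold_h) || threshold_h <= 0) abort("`threshold_h` must be positive")
  grid <- fix_grid()
  oc_all <- parse_clock_min(log$onset_clock)
  wc_all <- parse_clock_min(log$waking_clock)

  rows <- purrr::pmap(
    list(log$night_date, log$onset, log$waking, oc_all, wc_all, log$ambiguous),
    function(nd, onset, waking, oc, wc, amb) {
      if (isTRUE(amb) || is.na(oc) || is.na(wc)) {
        return(tibble::tibble(
          night_date = nd, deviation_onset_h = NA_real_,
          deviation_waking_h = NA_real_, flagged = TRUE,
          suggested_fix = "exclude_ambiguous"
        ))
      }
      dev_o <- min_dist_h(onset, bouts$start)
      dev_w <- min_dist_h(waking, bouts$end)
      flagged <- dev_o > threshold_h || dev_w > threshold_h
      fix <- "none"
      if (flagged) {
        cand <- purrr::pmap_dfr(
          grid[grid$label != "none", ],
          function(swap, flip_onset, flip_waking, label) {
            tr <- apply_fix_transform(nd, oc, wc, swap, flip_onset, flip_waking)
            tibble::tibble(
              label = label,
              dev_o = min_dist_h(tr$onset, bouts$start),
              dev_w = min_dist_h(tr$waking, bouts$end)
            )
          }
        )
        ok <- cand[cand$dev_o <= threshold_h & cand$dev_w <= threshold_h, ]
        fix <- if (nrow(ok)) ok$label[which.min(ok$dev_o + ok$dev_w)] else "exclude_ambiguous"
      }
      tibble::tibble(
        night_date = nd, deviation_onset_h = dev_o, deviation_waking_h = dev_w,
        flagged = flagged, suggested_fix = fix
      )
    }
  )
  dplyr::bind_rows(rows)
}

#' Apply unambiguous suggested log fixes
#'
#' Applies only single-transform suggestions (`am_pm_flip_onset`,
#' `am_pm_flip_waking`, `swap_onset_waking`) from [screen_sleep_log()] to the
#' log; compound suggestions (`am_pm_flip_both`, `flip_and_swap`) are left for
#' manual review, and `exclude_ambiguous` nights are marked ambiguous.
#'
#' @param log Parsed sleep log.
#' @param report Screening report from [screen_sleep_log()].
#' @return The log with corrected rows and an added logical column `fixed`.
#' @export
apply_log_fixes <- function(log, report) {
  log <- dplyr::left_join(
    log, report[, c("night_date", "suggested_fix")], by = "night_date"
  )
  log$suggested_fix[is.na(log$suggested_fix)] <- "none"
  log$fixed <- FALSE
  single <- c(
    am_pm_flip_onset = "flip_onset",
    am_pm_flip_waking = "flip_waking",
    swap_onset_waking = "swap"
  )
  for (i in seq_len(nrow(log))) {
    fx <- log$suggested_fix[i]
    if (fx %in% names(single)) {
      tr <- apply_fix_transform(
        log$night_date[i],
        parse_clock_min(log$onset_clock[i]),
        parse_clock_min(log$waking_clock[i]),
        swap = single[[fx]] == "swap",
        flip_onset = single[[fx]] == "flip_onset",
        flip_waking = single[[fx]] == "flip_waking"
      )
      log$onset[i] <- tr$onset
      log$waking[i] <- tr$waking
      log$onset_clock[i] <- format_clock(tr$onset_clock_min)
      log$waking_clock[i] <- format_clock(tr$waking_clock_min)
      log$fixed[i] <- TRUE
    } else if (fx == "exclude_ambiguous") {
      log$ambiguous[i] <- TRUE
      log$reason[i] <- "no qualifying log fix"
    }
  }
  dplyr::select(log, -"suggested_fix")
}
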