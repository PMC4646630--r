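#' Detect sustained-inactivity bouts
#'
#' Scans an epoch-level angle series for maximal runs of consecutive epochs in
#' which no change between successive epochs exceeds the angle threshold
#' (strictly: a run breaks only when `|angle[i+1] - angle[i]| >` threshold;
#' equality passes). Runs spanning at least the minimum bout duration are
#' returned as sustained-inactivity bouts — candidate sleep periods. Only
#' adjacent-epoch differences are tested, so slow drift below the threshold
#' per epoch can accumulate inside one bout. `NA` epochs (non-wear, undefined
#' angle) terminate runs and belong to no bout.
#'
#' A run of `k` epochs spans `k * epoch_s` seconds (the end of a bout is the
#' end of its last epoch), and qualifies when that span is at least
#' `min_bout_min` minutes.
#'
#' @param angles Angle series from [compute_angle_series()], or any tibble
#'   with `epoch_start` and `angle_deg` columns (epoch length taken from the
#'   `epoch_s` attribute, else from `config`).
#' @param config A [detection_config()]; uses `angle_threshold_deg`,
#'   `min_bout_min` and `epoch_s`.
#' @return A tibble with columns `bout_id`, `start`, `end` (POSIXct) and
#'   `duration_min`, disjoint and ordered by `start`. Zero rows when no run
#'   qualifies.
#' @examples
#' ep <- tibble::tibble(
#'   epoch_start = as.POSIXct("2013-02-07 23:00:00", tz = "UTC") + 5 * (0:119),
#'   angle_deg = 30
#' )
#' detect_bouts(ep) # one 10-minute bout
#' @export
detect_bouts <- function(angles, config = detection_config()) {
  if (!is.data.frame(angles) || !all(c("epoch_start", "angle_deg") %in% names(angles))) {
    abort("`angles` must have columns `epoch_start` and `angle_deg`")
  }
  if (nrow(angles) == 0L) abort("empty angle series")
  epoch_s <- attr(angles, "epoch_s") %||% config$epoch_s
  thr <- config$angle_threshold_deg
  min_span_s <- config$min_bout_min * 60

  ang <- angles$angle_deg
  n <- length(ang)

  empty <- tibble::tibble(
    bout_id = integer(),
    start = angles$epoch_start[0],
    end = angles$epoch_start[0],
    duration_min = double()
  )
  if (n * epoch_s < min_span_s) return(empty)

  d <- abs(diff(ang))
  new_run <- c(TRUE, is.na(d) | d > thr)
  start_i <- which(new_run)
  end_i <- c(start_i[-1] - 1L, n)
  keep <- !is.na(ang[start_i]) & (end_i - start_i + 1L) * epoch_s >= min_span_s
  start_i <- start_i[keep]
  end_i <- end_i[keep]
  if (!length(start_i)) return(empty)

  tibble::tibble(
    bout_id = seq_along(start_i),
    start = angles$epoch_start[start_i],
    end = angles$epoch_start[end_i] + epoch_s,
    duration_min = (end_i - start_i + 1L) * epoch_s / 60
  )
}
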