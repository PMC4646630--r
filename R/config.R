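#' Detector configuration
#'
#' Parameters of the sustained-inactivity detector. The defaults are the
#' reference configuration: a 5-s rolling median of each acceleration axis,
#' 5-s epochs, runs broken where the arm angle changes by more than 5 degrees
#' between successive epochs, and a minimum qualifying run span of 5 minutes.
#' A 10-minute minimum span is the standard stricter alternative; the grids
#' `c(3, 5, 7, 10, 15)` minutes and `c(3, 5, 10)` degrees are used for
#' validation sweeps.
#'
#' @param median_window_s Width of the centered per-axis rolling median, in
#'   seconds. Shrunk at the recording edges.
#' @param epoch_s Epoch length in seconds; per-sample angles are averaged into
#'   contiguous blocks of this length anchored at the recording start.
#' @param angle_threshold_deg Maximum absolute angle change (degrees) between
#'   successive epochs tolerated inside a bout; a strictly larger change
#'   breaks the run.
#' @param min_bout_min Minimum run span in minutes for a run to qualify as a
#'   sustained-inactivity bout. `min_bout_min * 60` must be a multiple of
#'   `epoch_s`.
#' @param dynamic_range_g Sensor dynamic range in g; samples outside
#'   `[-dynamic_range_g, dynamic_range_g]` are rejected.
#'
#' @return An object of class `detection_config` (a validated list).
#' @examples
#' detection_config()
#' detection_config(min_bout_min = 10)
#' @export
detection_config <- function(median_window_s = 5,
                             epoch_s = 5,
                             angle_threshold_deg = 5,
                             min_bout_min = 5,
                             dynamic_range_g = 8) {
  cfg <- list(
    median_window_s = median_window_s,
    epoch_s = epoch_s,
    angle_threshold_deg = angle_threshold_deg,
    min_bout_min = min_bout_min,
    dynamic_range_g = dynamic_range_g
  )
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive finite number", nm))
    }
  }
  if (abs((min_bout_min * 60) %% epoch_s) > 1e-9) {
    abort("`min_bout_min * 60` must be an integer multiple of `epoch_s`")
  }
  structure(cfg, class = "detection_config")
}

#' @export
print.detection_config <- function(x, ...) {
  cat("<detection_config>\n")
  cat(sprintf("  rolling median : %g s (centered, shrunk at edges)\n", x$median_window_s))
  cat(sprintf("  epoch length   : %g s\n", x$epoch_s))
  cat(sprintf("  angle threshold: %g deg\n", x$angle_threshold_deg))
  cat(sprintf("  minimum bout   : %g min\n", x$min_bout_min))
  cat(sprintf("  dynamic range  : +/- %g g\n", x$dynamic_range_g))
  invisible(x)
}

#' Read a detector configuration file
#'
#' Reads a plain `key = value` configuration file (one pair per line, `#`
#' comments allowed) with keys matching the arguments of
#' [detection_config()]. Keys not present keep their defaults.
#'
#' @param path Path to the configuration file.
#' @return A `detection_config`.
#' @export
read_detection_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) abort(sprintf("cannot parse config line: '%s'", ln))
    key <- trimws(kv[1])
    val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (is.na(val)) abort(sprintf("non-numeric value for '%s'", key))
    args[[key]] <- val
  }
  unknown <- setdiff(names(args), names(formals(detection_config)))
  if (length(unknown)) abort(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  do.call(detection_config, args)
}
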