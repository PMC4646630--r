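#' Epoch-level arm angle from raw acceleration
#'
#' Converts a raw tri-axial recording into the detector's working
#' representation: the arm angle (the angle of the z axis, perpendicular to
#' the skin surface, relative to the horizontal plane),
#' `atan(az / sqrt(ax^2 + ay^2)) * 180 / pi`, computed per sample from
#' centered rolling medians of each axis and then averaged over contiguous
#' fixed epochs anchored at the recording start. A trailing partial epoch is
#' dropped. The rolling median rejects brief spikes (a single-sample
#' artefact per window cannot move the median) and the angle depends only on
#' `az` and the horizontal magnitude, so it is insensitive to rotation about
#' the vertical.
#'
#' Epochs whose samples include non-worn periods (`wear == FALSE`) are set to
#' `NA`; so are epochs whose median acceleration vector is exactly zero
#' (undefined direction). `NA` epochs later terminate inactivity runs.
#'
#' @param raw Recording tibble with columns `timestamp`, `x`, `y`, `z` (g)
#'   and optionally `wear` (logical). Must be uniformly sampled.
#' @param config A [detection_config()].
#' @return A tibble with columns `epoch_start` (POSIXct, gap-free, spaced
#'   `epoch_s` apart) and `angle_deg` (degrees in `[-90, 90]` or `NA`), with
#'   attribute `epoch_s`.
#' @examples
#' raw <- tibble::tibble(
#'   timestamp = as.POSIXct("2013-02-07 12:00:00", tz = "UTC") + seq(0, 59.9, by = 0.1),
#'   x = 0, y = 0, z = 1
#' )
#' compute_angle_series(raw) # every epoch at +90 degrees
#' @export
compute_angle_series <- function(raw, config = detection_config()) {
  dt <- check_raw_recording(raw, config)
  n <- nrow(raw)
  if (is.na(dt)) abort("recording must contain more than one sample")
  duration <- n * dt
  if (duration < config$median_window_s) {
    abort("recording is shorter than the rolling-median window")
  }
  if (duration < config$epoch_s) {
    abort("recording is shorter than one epoch")
  }

  k <- max(1L, as.integer(round(config$median_window_s / dt)))
  if (k %% 2L == 0L) k <- k + 1L

  ang <- median_angle_c(raw$x, raw$y, raw$z, k)

  n_epochs <- floor(duration / config$epoch_s)
  spe <- config$epoch_s / dt # samples per epoch
  if (abs(spe - round(spe)) < 1e-8) {
    # integer samples-per-epoch: contiguous blocks
    spe <- as.integer(round(spe))
    used <- spe * n_epochs
    angle_epoch <- .colMeans(ang[seq_len(used)], spe, n_epochs)
    if ("wear" %in% names(raw)) {
      nonwear <- .colSums(as.numeric(!raw$wear[seq_len(used)]), spe, n_epochs)
      angle_epoch[nonwear > 0] <- NA_real_
    }
  } else {
    tt <- as.numeric(raw$timestamp)
    e <- floor((tt - tt[1]) / config$epoch_s)
    keep <- e < n_epochs
    e <- as.integer(e[keep]) + 1L
    sums <- rowsum(ang[keep], e, reorder = TRUE)
    counts <- tabulate(e, nbins = n_epochs)
    angle_epoch <- rep(NA_real_, n_epochs)
    angle_epoch[as.integer(rownames(sums))] <- sums[, 1] / counts[as.integer(rownames(sums))]
    if ("wear" %in% names(raw)) {
      nonwear <- rowsum(as.numeric(!raw$wear[keep]), e, reorder = TRUE)
      bad <- as.integer(rownames(nonwear))[nonwear[, 1] > 0]
      angle_epoch[bad] <- NA_real_
    }
  }

  out <- tibble::tibble(
    epoch_start = raw$timestamp[1] + (seq_len(n_epochs) - 1L) * config$epoch_s,
    angle_deg = angle_epoch
  )
  attr(out, "epoch_s") <- config$epoch_s
  out
}
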