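#' Read a raw accelerometer CSV
#'
#' Reads a raw tri-axial recording with header `timestamp,x,y,z[,wear]`:
#' ISO-8601 timestamps, acceleration in g per axis, and an optional logical
#' wear column (`TRUE` = device worn). Timestamps are treated as a
#' timezone-naive local clock and stored as UTC.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `timestamp` (POSIXct), `x`, `y`, `z` (g) and,
#'   if present in the file, `wear` (logical).
#' @seealso [read_raw_csv_chunked()] for multi-day files that should not be
#'   loaded whole.
#' @export
read_raw_csv <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      timestamp = readr::col_datetime(),
      x = readr::col_double(),
      y = readr::col_double(),
      z = readr::col_double(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
  need <- c("timestamp", "x", "y", "z")
  miss <- setdiff(need, names(raw))
  if (length(miss)) abort(paste("raw CSV is missing columns:", paste(miss, collapse = ", ")))
  if ("wear" %in% names(raw)) raw$wear <- as.logical(raw$wear)
  raw
}

#' Process a raw CSV in chunks
#'
#' Streaming contract for multi-day recordings: the file is read in chunks of
#' `chunk_size` rows and `callback(chunk, pos)` is invoked per chunk, so the
#' full signal never has to reside in memory. Chunk boundaries are the
#' caller's responsibility (e.g. carry the trailing `median_window_s` of
#' samples over to the next chunk before computing angles).
#'
#' @param path Path to the CSV file.
#' @param callback Function of `(chunk, pos)` applied to each chunk tibble.
#' @param chunk_size Rows per chunk.
#' @return Invisibly, `NULL`.
#' @export
read_raw_csv_chunked <- function(path, callback, chunk_size = 1e6) {
  readr::read_csv_chunked(
    path,
    callback = readr::SideEffectChunkCallback$new(callback),
    chunk_size = chunk_size,
    col_types = readr::cols(
      timestamp = readr::col_datetime(),
      x = readr::col_double(),
      y = readr::col_double(),
      z = readr::col_double(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
  invisible(NULL)
}

# Validate a raw recording tibble and return its sampling interval (seconds).
# Rejects empty input, non-finite samples (with a count), values beyond the
# dynamic range, and non-increasing timestamps.
check_raw_recording <- function(raw, config) {
  if (!is.data.frame(raw) || nrow(raw) == 0L) abort("empty recording")
  need <- c("timestamp", "x", "y", "z")
  miss <- setdiff(need, names(raw))
  if (length(miss)) abort(paste("recording is missing columns:", paste(miss, collapse = ", ")))
  chk <- check_axes_c(raw$x, raw$y, raw$z)
  if (chk$n_nonfinite > 0) {
    abort(sprintf("recording contains %d non-finite samples", chk$n_nonfinite))
  }
  if (chk$max_abs > config$dynamic_range_g) {
    abort(sprintf("samples exceed the +/- %g g dynamic range", config$dynamic_range_g))
  }
  tt <- as.numeric(raw$timestamp)
  n <- length(tt)
  if (n == 1L) return(NA_real_)
  med_dt <- (tt[n] - tt[1]) / (n - 1)
  if (med_dt <= 0) abort("timestamps must be strictly increasing")
  # uniformity check on a stride of anchor points: the mean step between
  # consecutive anchors must match the overall step, which catches gaps and
  # rate changes without touching all n diffs of a multi-day file
  idx <- unique(round(seq(1, n, length.out = min(n, 10001L))))
  step <- diff(tt[idx]) / diff(idx)
  if (any(step <= 0) || any(abs(step - med_dt) > 0.5 * med_dt)) {
    abort("recording is not uniformly sampled; gaps must be filled with NA wear before detection")
  }
  med_dt
}

#' Write detected bouts to CSV
#'
#' @param bouts A bout tibble from [detect_bouts()].
#' @param path Output path; columns `bout_id,start,end,duration_min`.
#' @return Invisibly, `bouts`.
#' @export
write_bouts_csv <- function(bouts, path) {
  out <- dplyr::mutate(
    bouts,
    start = format(.data$start, "%Y-%m-%dT%H:%M:%S"),
    end = format(.data$end, "%Y-%m-%dT%H:%M:%S")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(bouts)
}

#' Read bouts from CSV
#'
#' @param path CSV written by [write_bouts_csv()].
#' @return A bout tibble (`bout_id`, `start`, `end`, `duration_min`).
#' @export
read_bouts_csv <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      bout_id = readr::col_integer(),
      start = readr::col_datetime(),
      end = readr::col_datetime(),
      duration_min = readr::col_double()
    ),
    progress = FALSE
  )
}
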