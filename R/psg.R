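#' Construct a hypnogram
#'
#' A polysomnography hypnogram: scored 30-s epochs over the total sleep
#' period (lights out until final waking). Stages use the standard labels
#' `W, N1, N2, N3, REM`; sleep is any non-`W` stage.
#'
#' @param stages Tibble with columns `epoch_start` (POSIXct) and `stage`, or
#'   a character vector of stages (epoch starts then derived from
#'   `lights_out`).
#' @param lights_out,wake_up POSIXct bounds of the total sleep period.
#' @param epoch_s Scoring epoch length in seconds (default 30).
#' @return A tibble of class `hypnogram` with attributes `lights_out`,
#'   `wake_up`, `epoch_s`.
#' @export
hypnogram <- function(stages, lights_out, wake_up, epoch_s = 30) {
  if (is.character(stages)) {
    stages <- tibble::tibble(
      epoch_start = lights_out + (seq_along(stages) - 1L) * epoch_s,
      stage = stages
    )
  }
  if (!all(c("epoch_start", "stage") %in% names(stages))) {
    abort("`stages` must have columns `epoch_start` and `stage`")
  }
  bad <- setdiff(unique(stages$stage), c("W", "N1", "N2", "N3", "REM"))
  if (length(bad)) abort(paste("unknown sleep stages:", paste(bad, collapse = ", ")))
  if (wake_up <= lights_out) abort("`wake_up` must be after `lights_out`")
  out <- tibble::as_tibble(stages)
  attr(out, "lights_out") <- lights_out
  attr(out, "wake_up") <- wake_up
  attr(out, "epoch_s") <- epoch_s
  class(out) <- c("hypnogram", class(out))
  out
}

#' Read a hypnogram CSV with its sidecar metadata
#'
#' @param path CSV with header `epoch_start,stage`.
#' @param meta_path JSON sidecar with fields `lights_out`, `wake_up` and
#'   optionally `epoch_s`; defaults to `<path without extension>.json`.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.[^.]+$", ".json", path)
  stages <- readr::read_csv(
    path,
    col_types = readr::cols(epoch_start = readr::col_datetime(),
                            stage = readr::col_character()),
    progress = FALSE
  )
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  hypnogram(
    stages,
    lights_out = as.POSIXct(meta$lights_out, tz = "UTC"),
    wake_up = as.POSIXct(meta$wake_up, tz = "UTC"),
    epoch_s = meta$epoch_s %||% 30
  )
}

#' Epoch-level sleep/wake classification against polysomnography
#'
#' Pairs the detector output with a hypnogram, restricted to the total sleep
#' period `[lights_out, wake_up)`. Truth per 30-s scoring epoch is sleep for
#' any non-wake stage. The detector prediction for a scoring epoch is sleep
#' when at least 4 of its six 5-s detector epochs lie inside a
#' sustained-inactivity bout (majority rule); with `grid = "5s"` the scoring
#' labels are instead expanded to the 5-s detector grid and compared
#' one-to-one.
#'
#' @param bouts Bout tibble ([detect_bouts()]).
#' @param hyp A [hypnogram()].
#' @param grid `"30s"` (majority vote, default) or `"5s"` (expand PSG labels).
#' @param detector_epoch_s Detector epoch length in seconds (default 5).
#' @return A tibble with columns `epoch_start`, `truth_sleep`, `pred_sleep`
#'   and attribute `epoch_s` (30 or 5 according to `grid`).
#' @export
epoch_classification <- function(bouts, hyp, grid = c("30s", "5s"),
                                 detector_epoch_s = 5) {
  grid <- match.arg(grid)
  lights_out <- attr(hyp, "lights_out")
  wake_up <- attr(hyp, "wake_up")
  psg_epoch_s <- attr(hyp, "epoch_s") %||% 30

  keep <- hyp$epoch_start >= lights_out & hyp$epoch_start < wake_up
  hh <- hyp[keep, ]
  if (nrow(hh) == 0L) abort("hypnogram does not overlap the total sleep period")

  in_bout <- function(t) {
    # t: numeric midpoints of detector sub-epochs
    res <- rep(FALSE, length(t))
    for (i in seq_len(nrow(bouts))) {
      res <- res | (t >= as.numeric(bouts$start[i]) & t < as.numeric(bouts$end[i]))
    }
    res
  }

  n_sub <- as.integer(round(psg_epoch_s / detector_epoch_s))
  offsets <- (seq_len(n_sub) - 1L) * detector_epoch_s + detector_epoch_s / 2

  if (grid == "30s") {
    base <- as.numeric(hh$epoch_start)
    votes <- rowSums(vapply(offsets, function(o) in_bout(base + o),
                            logical(nrow(hh))))
    out <- tibble::tibble(
      epoch_start = hh$epoch_start,
      truth_sleep = hh$stage != "W",
      pred_sleep = votes >= ceiling(2 / 3 * n_sub)
    )
    attr(out, "epoch_s") <- psg_epoch_s
  } else {
    base <- rep(as.numeric(hh$epoch_start), each = n_sub) +
      rep((seq_len(n_sub) - 1L) * detector_epoch_s, times = nrow(hh))
    out <- tibble::tibble(
      epoch_start = as.POSIXct(base, tz = "UTC", origin = "1970-01-01"),
      truth_sleep = rep(hh$stage != "W", each = n_sub),
      pred_sleep = in_bout(base + detector_epoch_s / 2)
    )
    attr(out, "epoch_s") <- detector_epoch_s
  }
  out
}

#' Classification metrics per patient
#'
#' Accuracy, sensitivity and specificity of the binary sleep/wake
#' classification, and the bias in estimated sleep duration (predicted minus
#' polysomnography sleep epochs, in minutes). Sensitivity is with respect to
#' sleep (`TP / (TP + FN)`), specificity with respect to wake
#' (`TN / (TN + FP)`). A patient with no truth-wake epochs has undefined
#' specificity (`NA`, flagged), and likewise for sensitivity without
#' truth-sleep epochs.
#'
#' @param paired Epoch classification tibble from [epoch_classification()],
#'   optionally with a `patient` column; without one, a single patient is
#'   assumed.
#' @param epoch_s Epoch length in seconds; defaults to the `epoch_s`
#'   attribute of `paired`.
#' @return A tibble with one row per patient: `patient`, `accuracy_pct`,
#'   `sensitivity_pct`, `specificity_pct`, `bias_min`, `degenerate`.
#' @export
classification_metrics <- function(paired, epoch_s = NULL) {
  epoch_s <- epoch_s %||% attr(paired, "epoch_s") %||% 30
  if (!"patient" %in% names(paired)) paired$patient <- 1L
  dplyr::group_by(paired, .data$patient) |>
    dplyr::summarise(
      tp = sum(.data$truth_sleep & .data$pred_sleep),
      fn = sum(.data$truth_sleep & !.data$pred_sleep),
      tn = sum(!.data$truth_sleep & !.data$pred_sleep),
      fp = sum(!.data$truth_sleep & .data$pred_sleep),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      accuracy_pct = 100 * (.data$tp + .data$tn) /
        (.data$tp + .data$fn + .data$tn + .data$fp),
      sensitivity_pct = ifelse(.data$tp + .data$fn > 0,
                               100 * .data$tp / (.data$tp + .data$fn), NA_real_),
      specificity_pct = ifelse(.data$tn + .data$fp > 0,
                               100 * .data$tn / (.data$tn + .data$fp), NA_real_),
      bias_min = ((.data$tp + .data$fp) - (.data$tp + .data$fn)) * epoch_s / 60,
      degenerate = .data$tp + .data$fn == 0 | .data$tn + .data$fp == 0
    ) |>
    dplyr::select(-"tp", -"fn", -"tn", -"fp")
}

#' Across-patient summary of validation metrics
#'
#' @param metrics Per-patient metrics from [classification_metrics()].
#' @return A tibble with one row per metric: `metric`, `mean`, `sd`,
#'   `n_patients` (mean and SD between patients, `NA` metrics dropped).
#' @export
metrics_summary <- function(metrics) {
  long <- tidyr::pivot_longer(
    metrics,
    c("accuracy_pct", "sensitivity_pct", "specificity_pct", "bias_min"),
    names_to = "metric", values_to = "value"
  )
  dplyr::group_by(long, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      n_patients = sum(!is.na(.data$value)),
      .groups = "drop"
    )
}

#' Sweep the time-window and angle-threshold grid
#'
#' Re-runs bout detection and epoch-level validation for every combination of
#' minimum bout duration and angle threshold, on one recording/hypnogram
#' pair. The angle series is computed once (it does not depend on either
#' parameter). Because bouts at a stricter threshold are always contained in
#' bouts at a looser one, predicted sleep time is non-increasing in window
#' length and non-decreasing in angle threshold, so sensitivity to sleep
#' falls and specificity rises down each fixed-angle column.
#'
#' @param raw Raw recording tibble (see [compute_angle_series()]), or a
#'   precomputed angle series (tibble with `angle_deg`).
#' @param hyp A [hypnogram()].
#' @param windows Minimum bout durations to evaluate, minutes.
#' @param angles Angle thresholds to evaluate, degrees.
#' @param config Base [detection_config()] (median window and epoch length).
#' @param grid Epoch comparison grid, see [epoch_classification()].
#' @return A tibble with one row per `(window_min, angle_deg)` cell:
#'   the four metrics plus `pred_sleep_epochs`.
#' @export
parameter_sweep <- function(raw, hyp, windows = c(3, 5, 7, 10, 15),
                            angles = c(3, 5, 10),
                            config = detection_config(), grid = "30s") {
  series <- if ("angle_deg" %in% names(raw)) raw else compute_angle_series(raw, config)
  cells <- tidyr::expand_grid(window_min = windows, angle_deg = angles)
  purrr::pmap_dfr(cells, function(window_min, angle_deg) {
    cfg <- detection_config(
      median_window_s = config$median_window_s,
      epoch_s = config$epoch_s,
      angle_threshold_deg = angle_deg,
      min_bout_min = window_min,
      dynamic_range_g = config$dynamic_range_g
    )
    bouts <- detect_bouts(series, cfg)
    paired <- epoch_classification(bouts, hyp, grid = grid,
                                   detector_epoch_s = cfg$epoch_s)
    met <- classification_metrics(paired)
    dplyr::mutate(
      dplyr::select(met, -"patient"),
      window_min = window_min, angle_deg = angle_deg,
      pred_sleep_epochs = sum(paired$pred_sleep),
      .before = 1
    )
  })
}
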