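#' Discard fixations falling too far outside the stimulus image
#'
#' A fixation is discarded when its centroid lies more than
#' `margin_frac` of the corresponding image dimension outside the image
#' rectangle, per axis: the keep region is `image_rect` expanded by
#' `margin_frac * width` horizontally and `margin_frac * height`
#' vertically on each side (default 20%). Kept fixations retain their
#' original centroids; whether a kept centroid was off-image (and will be
#' clamped at scoring time) is recorded in an `off_image` column.
#'
#' @param fixations A `gaze_events` tibble (saccade rows are ignored and
#'   dropped).
#' @param image_rect Stimulus rectangle, `c(x, y, w, h)` in screen pixels.
#' @param margin_frac Tolerated overshoot as a fraction of the image
#'   dimension, in `[0, 1]`.
#' @return The kept fixation rows, with an added logical `off_image`.
#' @export
filter_fixations <- function(fixations, image_rect, margin_frac = 0.20) {
  if (margin_frac < 0 || margin_frac > 1) {
    stop("margin_frac must be in [0, 1]", call. = FALSE)
  }
  rect <- as_rect(image_rect)
  if (rect$w <= 0 || rect$h <= 0) {
    stop("degenerate image_rect: width and height must be positive", call. = FALSE)
  }
  fx <- dplyr::filter(tibble::as_tibble(fixations), .data$type == "fixation")
  mx <- margin_frac * rect$w
  my <- margin_frac * rect$h
  keep <- fx$x_px >= rect$x - mx & fx$x_px <= rect$x + rect$w + mx &
    fx$y_px >= rect$y - my & fx$y_px <= rect$y + rect$h + my
  fx <- fx[keep & !is.na(keep), , drop = FALSE]
  fx$off_image <- fx$x_px < rect$x | fx$x_px > rect$x + rect$w - 1 |
    fx$y_px < rect$y | fx$y_px > rect$y + rect$h - 1
  fx
}

#' Fixation saliency value: map intensity at a fixation center
#'
#' The fixation centroid is translated into map coordinates via the
#' stimulus rectangle, looked up at the nearest pixel, and that pixel's
#' intensity is the fixation saliency value. Centroids kept by the margin
#' rule but lying off the image are clamped to the nearest in-map pixel
#' (maps exist only over the image; clamping is the minimal-assumption
#' rule). No interpolation is performed: intensities are defined per
#' pixel. When the map resolution differs from the displayed rectangle the
#' centroid is rescaled accordingly.
#'
#' @param x_px,y_px Fixation centroid(s) in screen pixels (vectorized).
#' @param map A normalized, non-constant [saliency_map()].
#' @param image_rect Stimulus rectangle `c(x, y, w, h)` in screen pixels.
#' @return Integer intensities in 0..255.
#' @export
fixation_value <- function(x_px, y_px, map, image_rect) {
  if (!inherits(map, "saliency_map")) stop("`map` must be a saliency_map", call. = FALSE)
  if (!attr(map, "normalized")) {
    stop("map must be normalized (run smooth_and_normalize first)", call. = FALSE)
  }
  if (attr(map, "constant")) {
    stop(sprintf("map '%s' is constant and carries no feature signal; refusing to score",
                 attr(map, "feature_label")), call. = FALSE)
  }
  rect <- as_rect(image_rect)
  sx <- map_width(map) / rect$w
  sy <- map_height(map) / rect$h
  col <- round((x_px - rect$x) * sx) + 1
  row <- round((y_px - rect$y) * sy) + 1
  col <- pmin(pmax(col, 1), map_width(map))
  row <- pmin(pmax(row, 1), map_height(map))
  m <- unclass_map(map)
  as.numeric(m[cbind(row, col)])
}

#' Score a session: fixation saliency records and participant summaries
#'
#' For each trial, fixations whose temporal midpoint falls inside the
#' trial's display interval are selected, filtered by the out-of-image
#' margin rule, and scored against every feature map available for that
#' trial's image. Trials in which no fixation survives are discarded from
#' averaging. Per feature, the per-image mean is computed first and the
#' participant's overall mean is the unweighted mean of per-image means
#' (so long trials do not dominate).
#'
#' @param recording A [gaze_recording()] (for participant metadata and
#'   trials), or `NULL` if `trials` and metadata are given explicitly.
#' @param events A `gaze_events` tibble from [detect_events()].
#' @param manifest Map manifest tibble with columns `image_id`,
#'   `feature_label` and a `map` list-column of normalized
#'   [saliency_map()] objects (see [read_map_manifest()]). (image,
#'   feature) pairs missing from the manifest are skipped with a warning.
#' @param margin_frac Out-of-image tolerance passed to
#'   [filter_fixations()].
#' @param trials,participant_id,group_label Overrides when `recording` is
#'   `NULL`.
#' @return A list with tibbles `records` (participant, group, image,
#'   feature, fixation_index, value, off_image) and `summaries`
#'   (participant, group, feature, overall_mean, n_trials, n_fixations).
#' @export
score_session <- function(recording, events, manifest, margin_frac = 0.20,
                          trials = NULL, participant_id = NULL,
                          group_label = NULL) {
  if (!is.null(recording)) {
    stopifnot(inherits(recording, "gaze_recording"))
    trials <- trials %||% recording$trials
    participant_id <- participant_id %||% recording$participant_id
    group_label <- group_label %||% recording$group_label
  }
  if (is.null(trials) || !nrow(trials)) {
    stop("score_session requires a trial table", call. = FALSE)
  }
  trials <- validate_trials(trials)
  if (!"map" %in% names(manifest)) {
    stop("manifest must carry loaded maps in a `map` list-column", call. = FALSE)
  }

  fix <- dplyr::filter(tibble::as_tibble(events), .data$type == "fixation")
  fix$mid_ms <- (fix$onset_ms + fix$offset_ms) / 2

  records <- list()
  for (ti in seq_len(nrow(trials))) {
    tr <- trials[ti, ]
    rect <- c(x = tr$rect_x, y = tr$rect_y, w = tr$rect_w, h = tr$rect_h)
    in_trial <- fix[fix$mid_ms >= tr$onset_ms & fix$mid_ms < tr$offset_ms, ]
    if (!nrow(in_trial)) next
    kept <- filter_fixations(in_trial, rect, margin_frac)
    if (!nrow(kept)) next   # trial without valid fixations: discarded
    feats <- manifest[manifest$image_id == tr$image_id, ]
    if (!nrow(feats)) {
      warning(sprintf("no maps in manifest for image '%s'; trial skipped",
                      tr$image_id), call. = FALSE)
      next
    }
    for (fi in seq_len(nrow(feats))) {
      vals <- fixation_value(kept$x_px, kept$y_px, feats$map[[fi]], rect)
      records[[length(records) + 1L]] <- tibble::tibble(
        participant_id = participant_id, group_label = group_label,
        image_id = tr$image_id, feature_label = feats$feature_label[fi],
        trial_index = ti, fixation_index = seq_len(nrow(kept)),
        value = vals, off_image = kept$off_image)
    }
  }

  if (!length(records)) {
    records <- tibble::tibble(
      participant_id = character(), group_label = character(),
      image_id = character(), feature_label = character(),
      trial_index = integer(), fixation_index = integer(),
      value = numeric(), off_image = logical())
    summaries <- tibble::tibble(
      participant_id = character(), group_label = character(),
      feature_label = character(), overall_mean = numeric(),
      n_trials = integer(), n_fixations = integer())
    return(list(records = records, summaries = summaries))
  }

  records <- dplyr::bind_rows(records)
  per_image <- records |>
    dplyr::group_by(.data$participant_id, .data$group_label,
                    .data$feature_label, .data$image_id, .data$trial_index) |>
    dplyr::summarise(image_mean = mean(.data$value),
                     n_fix = dplyr::n(), .groups = "drop")
  summaries <- per_image |>
    dplyr::group_by(.data$participant_id, .data$group_label,
                    .data$feature_label) |>
    dplyr::summarise(overall_mean = mean(.data$image_mean),
                     n_trials = dplyr::n_distinct(.data$trial_index),
                     n_fixations = sum(.data$n_fix), .groups = "drop")
  list(records = records, summaries = summaries)
}

#' Score a whole cohort of recordings
#'
#' Runs [detect_events()] and [score_session()] over a list of recordings
#' and row-binds the results.
#'
#' @param recordings List of [gaze_recording()] objects.
#' @param manifest Loaded map manifest (see [score_session()]).
#' @param params [detection_params()].
#' @param margin_frac Out-of-image tolerance.
#' @param denoise Apply [heuristic_denoise()] before detection?
#' @return A list with `records` and `summaries` tibbles across the
#'   cohort, plus `events` (list of per-participant event tibbles).
#' @export
score_cohort <- function(recordings, manifest, params = detection_params(),
                         margin_frac = 0.20, denoise = TRUE) {
  out <- purrr::map(recordings, function(rec) {
    comp <- binocular_composite(rec)
    if (denoise) comp <- heuristic_denoise(comp, params$denoise_window_samples)
    ev <- detect_events(comp, rec$geometry, params, rec$sample_rate_hz)
    sc <- score_session(rec, ev, manifest, margin_frac)
    list(events = ev, records = sc$records, summaries = sc$summaries)
  })
  list(records = dplyr::bind_rows(purrr::map(out, "records")),
       summaries = dplyr::bind_rows(purrr::map(out, "summaries")),
       events = purrr::map(out, "events"))
}

#' Write scoring outputs
#'
#' Records CSV: `participant_id,group,image_id,feature,fixation_index,value`.
#' Summary CSV: `participant_id,group,feature,overall_mean,n_trials,n_fixations`.
#'
#' @param scores Result of [score_session()] or [score_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scores_csv <- function(scores, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec_path <- file.path(dir, "fixation_saliency_records.csv")
  sum_path <- file.path(dir, "participant_feature_summaries.csv")
  rec <- dplyr::rename(scores$records, group = "group_label",
                       feature = "feature_label")
  readr::write_csv(rec, rec_path, progress = FALSE)
  smy <- dplyr::rename(scores$summaries, group = "group_label",
                       feature = "feature_label")
  readr::write_csv(smy, sum_path, progress = FALSE)
  invisible(c(records = rec_path, summaries = sum_path))
}
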