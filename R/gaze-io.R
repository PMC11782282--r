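#' Assemble a gaze recording
#'
#' Bundles a timestamped binocular sample stream, its trial segmentation and
#' the viewing geometry for one participant session. Samples where both eyes
#' are invalid are retained but flagged; timestamps must be strictly
#' increasing and the median inter-sample interval must agree with the
#' nominal sample rate within 10%.
#'
#' @param samples Tibble with columns `t_ms`, `lx`, `ly`, `rx`, `ry`,
#'   `lvalid`, `rvalid`. Coordinates of an invalid eye may be `NA`.
#' @param geometry A [screen_geometry()].
#' @param sample_rate_hz Nominal sampling rate, Hz (research-grade video
#'   eye trackers record at 500 Hz).
#' @param trials Optional tibble of trial segments with columns `image_id`,
#'   `onset_ms`, `offset_ms`, `rect_x`, `rect_y`, `rect_w`, `rect_h`.
#' @param participant_id,group_label Participant metadata; `group_label` is
#'   free text (conventionally `"cvi"` or `"control"`).
#'
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(samples, geometry, sample_rate_hz,
                           trials = NULL, participant_id = NA_character_,
                           group_label = NA_character_) {
  assert_geometry(geometry)
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be strictly positive", call. = FALSE)
  }
  samples <- validate_gaze_samples(samples)
  if (nrow(samples) > 1) {
    med_isi <- stats::median(diff(samples$t_ms))
    nominal <- 1000 / sample_rate_hz
    if (abs(med_isi / nominal - 1) > 0.10) {
      warning(sprintf(
        "median inter-sample interval %.3f ms deviates >10%% from nominal %.3f ms",
        med_isi, nominal), call. = FALSE)
    }
  }
  if (!is.null(trials)) trials <- validate_trials(trials, geometry)
  structure(
    list(participant_id = participant_id, group_label = group_label,
         sample_rate_hz = sample_rate_hz, geometry = geometry,
         samples = samples, trials = trials),
    class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> participant %s (%s): %d samples @ %g Hz, %d trial(s)\n",
              x$participant_id, x$group_label, nrow(x$samples),
              x$sample_rate_hz,
              if (is.null(x$trials)) 0L else nrow(x$trials)))
  invisible(x)
}

gaze_sample_cols <- c("t_ms", "lx", "ly", "rx", "ry", "lvalid", "rvalid")

validate_gaze_samples <- function(samples) {
  missing <- setdiff(gaze_sample_cols, names(samples))
  if (length(missing)) {
    stop("gaze samples are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  samples <- tibble::as_tibble(samples)[gaze_sample_cols]
  if (any(diff(samples$t_ms) <= 0)) {
    bad <- which(diff(samples$t_ms) <= 0)[1] + 1L
    stop(sprintf("timestamps must be strictly increasing (violated at row %d)", bad),
         call. = FALSE)
  }
  samples$lvalid <- as.logical(samples$lvalid) & is.finite(samples$lx) & is.finite(samples$ly)
  samples$rvalid <- as.logical(samples$rvalid) & is.finite(samples$rx) & is.finite(samples$ry)
  samples
}

trial_cols <- c("image_id", "onset_ms", "offset_ms",
                "rect_x", "rect_y", "rect_w", "rect_h")

validate_trials <- function(trials, geometry = NULL) {
  missing <- setdiff(trial_cols, names(trials))
  if (length(missing)) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  trials <- tibble::as_tibble(trials)[trial_cols]
  if (any(trials$offset_ms <= trials$onset_ms)) {
    stop("trial offset_ms must exceed onset_ms", call. = FALSE)
  }
  if (!is.null(geometry)) {
    out <- trials$rect_x < 0 | trials$rect_y < 0 |
      trials$rect_x + trials$rect_w > geometry$width_px |
      trials$rect_y + trials$rect_h > geometry$height_px
    if (any(out)) {
      warning("trial image_rect extends beyond screen bounds for trial(s): ",
              paste(trials$image_id[out], collapse = ", "), call. = FALSE)
    }
  }
  trials
}

#' Read / write gaze sample CSV
#'
#' The native gaze dialect is a plain CSV with header
#' `t_ms,lx,ly,rx,ry,lvalid,rvalid`: timestamp in ms, per-eye x/y in screen
#' pixels (empty when the eye is untracked) and 0/1 validity flags.
#' Vendor-specific binary or ASC exports are deliberately out of scope; the
#' expectation is a one-off conversion into this documented dialect.
#'
#' @param path File path.
#' @param geometry A [screen_geometry()].
#' @param sample_rate Nominal sampling rate, Hz.
#' @param trials Optional trial table (see [read_trials_csv()]).
#' @param participant_id,group_label Metadata attached to the recording.
#' @return `read_gaze_csv()` returns a [gaze_recording()];
#'   `write_gaze_csv()` returns `path` invisibly.
#' @export
read_gaze_csv <- function(path, geometry, sample_rate, trials = NULL,
                          participant_id = NA_character_,
                          group_label = NA_character_) {
  if (!file.exists(path)) stop("gaze file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_double()))
  missing <- setdiff(gaze_sample_cols, names(raw))
  if (length(missing)) {
    stop(sprintf("gaze CSV %s is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  gaze_recording(raw, geometry, sample_rate, trials = trials,
                 participant_id = participant_id, group_label = group_label)
}

#' @rdname read_gaze_csv
#' @param recording A [gaze_recording()].
#' @export
write_gaze_csv <- function(recording, path) {
  stopifnot(inherits(recording, "gaze_recording"))
  out <- recording$samples
  out$lvalid <- as.integer(out$lvalid)
  out$rvalid <- as.integer(out$rvalid)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write trial segmentation CSV
#'
#' Header `image_id,onset_ms,offset_ms,rect_x,rect_y,rect_w,rect_h`; the
#' rect fields give the displayed stimulus rectangle in screen pixels.
#'
#' @param path File path.
#' @return A tibble of trial segments.
#' @export
read_trials_csv <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           image_id = readr::col_character(),
                           .default = readr::col_double()))
  validate_trials(raw)
}

#' @rdname read_trials_csv
#' @param trials A trial tibble.
#' @export
write_trials_csv <- function(trials, path) {
  readr::write_csv(validate_trials(trials), path, progress = FALSE)
  invisible(path)
}

#' Composite the two eyes into a single gaze stream
#'
#' When both eyes are tracked their positions are averaged into a composite
#' gaze position; when exactly one eye is valid that eye's position is used
#' unchanged (monocular recordings, e.g. from the fixating eye in
#' strabismus, are first-class); when neither is valid the sample is flagged
#' invalid and its position is `NA`.
#'
#' @param samples A gaze sample tibble (columns `t_ms`, `lx`, `ly`, `rx`,
#'   `ry`, `lvalid`, `rvalid`) or a [gaze_recording()].
#' @return A tibble with columns `t_ms`, `x_px`, `y_px`, `valid`.
#' @export
binocular_composite <- function(samples) {
  if (inherits(samples, "gaze_recording")) samples <- samples$samples
  samples <- validate_gaze_samples(samples)
  both <- samples$lvalid & samples$rvalid
  lonly <- samples$lvalid & !samples$rvalid
  ronly <- samples$rvalid & !samples$lvalid
  x <- rep(NA_real_, nrow(samples))
  y <- rep(NA_real_, nrow(samples))
  x[both] <- (samples$lx[both] + samples$rx[both]) / 2
  y[both] <- (samples$ly[both] + samples$ry[both]) / 2
  x[lonly] <- samples$lx[lonly]; y[lonly] <- samples$ly[lonly]
  x[ronly] <- samples$rx[ronly]; y[ronly] <- samples$ry[ronly]
  tibble::tibble(t_ms = samples$t_ms, x_px = x, y_px = y,
                 valid = both | lonly | ronly)
}
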