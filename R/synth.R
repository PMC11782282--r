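#' Synthetic raw feature maps
#'
#' Generates raw (real-valued, 0..1) saliency grids of the kinds the study
#' vocabulary needs: Gaussian `blob` maps (objects, faces, colored
#' regions), geometry-aware sinusoidal `grating` maps (orientation), hard
#' `field_half` indicator maps (visual-field preference, including a
#' center/periphery annulus split) and `background` maps (complement of a
#' blob foreground).
#'
#' @param kind One of `"blob"`, `"grating"`, `"field_half"`,
#'   `"background"`.
#' @param width,height Map size in pixels.
#' @param centers For blob/background: tibble or data.frame with columns
#'   `x`, `y` (0-based pixel coordinates within the map) and optionally
#'   `sigma` (px, default `width/10`).
#' @param side For `field_half`: `"left"`, `"right"`, `"upper"`,
#'   `"lower"`, `"center"` or `"periphery"` (center = inner half-radius
#'   disc around the map center).
#' @param cpd,geometry,image_rect For `grating`: target spatial frequency
#'   in cycles per degree under the given viewing geometry; the number of
#'   cycles across the image is rounded to an integer so the grating is a
#'   single Fourier line.
#' @param along Grating axis: variation along `"x"` (vertical bars) or
#'   `"y"`.
#' @return Numeric matrix (rows = y, cols = x) with values in `[0, 1]`.
#'   For gratings the realized frequency is attached as attribute
#'   `cycles`.
#' @export
make_feature_map <- function(kind = c("blob", "grating", "field_half",
                                      "background"),
                             width, height, centers = NULL, side = "left",
                             cpd = NULL, geometry = NULL, image_rect = NULL,
                             along = c("x", "y")) {
  kind <- match.arg(kind)
  along <- match.arg(along)
  if (width <= 0 || height <= 0) stop("map size must be positive", call. = FALSE)
  xs <- seq_len(width) - 1
  ys <- seq_len(height) - 1
  switch(kind,
    blob = blob_map(width, height, centers),
    background = 1 - blob_map(width, height, centers),
    field_half = {
      m <- matrix(0, height, width)
      cx <- (width - 1) / 2; cy <- (height - 1) / 2
      switch(side,
        left = { m[, xs < cx] <- 1 },
        right = { m[, xs > cx] <- 1 },
        upper = { m[ys < cy, ] <- 1 },
        lower = { m[ys > cy, ] <- 1 },
        center = {
          r <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
          m[r <= min(cx, cy) / 2] <- 1
        },
        periphery = {
          r <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
          m[r > min(cx, cy) / 2] <- 1
        },
        stop("unknown field side: ", side, call. = FALSE))
      m
    },
    grating = {
      if (is.null(cpd) || is.null(geometry) || is.null(image_rect)) {
        stop("grating maps need cpd, geometry and image_rect", call. = FALSE)
      }
      scale <- cpd_per_cycle(geometry, image_rect)
      cycles <- round(cpd / scale[[along]])
      if (cycles < 1) stop("requested cpd is below one cycle across the image",
                           call. = FALSE)
      phase <- if (along == "x") {
        matrix(rep(xs / width, each = height), height, width)
      } else {
        matrix(rep(ys / height, times = width), height, width)
      }
      m <- 0.5 + 0.5 * sin(2 * pi * cycles * phase)
      attr(m, "cycles") <- cycles
      m
    })
}

blob_map <- function(width, height, centers) {
  if (is.null(centers) || !nrow(centers)) {
    stop("blob/background maps need a `centers` table", call. = FALSE)
  }
  xs <- seq_len(width) - 1
  ys <- seq_len(height) - 1
  m <- matrix(0, height, width)
  sig <- centers$sigma %||% rep(width / 10, nrow(centers))
  for (i in seq_len(nrow(centers))) {
    m <- m + exp(-outer((ys - centers$y[i])^2, (xs - centers$x[i])^2, `+`) /
                   (2 * sig[i]^2))
  }
  m / max(m)
}

#' Simulated viewer profile
#'
#' A viewer is characterized by attention weights over feature maps:
#' fixation targets are sampled with probability proportional to the
#' weighted mixture of map intensities, with the unallocated remainder
#' `1 - sum(weights)` spread uniformly over the image (idle exploration).
#' Fixation durations are truncated-normal (floor `min_fixation_ms`, so a
#' floor below the detector's 100 ms minimum deliberately produces some
#' undetectable fixations); saccades between targets take a fixed
#' transition time; optional Gaussian jitter is added per sample and per
#' eye.
#'
#' @param label Profile label (`"cvi_like"`, `"control_like"`, or custom).
#' @param attention_weights Named non-negative numeric vector over feature
#'   labels, summing to at most 1.
#' @param fixation_duration_mean_ms,fixation_duration_sd_ms Truncated
#'   normal duration parameters, ms.
#' @param min_fixation_ms Truncation floor, ms (>= 1).
#' @param saccade_duration_ms Saccade transition time, ms.
#' @param gaze_noise_deg Per-sample, per-axis Gaussian jitter SD, degrees.
#' @return A list of class `viewer_profile`.
#' @export
viewer_profile <- function(label = "custom", attention_weights,
                           fixation_duration_mean_ms = 250,
                           fixation_duration_sd_ms = 50,
                           min_fixation_ms = 80,
                           saccade_duration_ms = 30,
                           gaze_noise_deg = 0) {
  if (is.null(names(attention_weights)) || any(names(attention_weights) == "")) {
    stop("attention_weights must be a named vector over feature labels",
         call. = FALSE)
  }
  if (any(attention_weights < 0)) stop("attention weights must be >= 0", call. = FALSE)
  if (sum(attention_weights) > 1 + 1e-9) {
    stop("attention weights must sum to at most 1", call. = FALSE)
  }
  if (fixation_duration_mean_ms < min_fixation_ms) {
    stop("mean fixation duration must be at least the truncation floor",
         call. = FALSE)
  }
  if (gaze_noise_deg < 0 || min_fixation_ms < 1 || saccade_duration_ms <= 0) {
    stop("invalid viewer profile parameter", call. = FALSE)
  }
  structure(list(label = label, attention_weights = attention_weights,
                 fixation_duration_mean_ms = fixation_duration_mean_ms,
                 fixation_duration_sd_ms = fixation_duration_sd_ms,
                 min_fixation_ms = min_fixation_ms,
                 saccade_duration_ms = saccade_duration_ms,
                 gaze_noise_deg = gaze_noise_deg),
            class = "viewer_profile")
}

#' Default group profiles
#'
#' Fixture profiles mirroring the anticipated group contrast: the
#' CVI-like viewer weights lower-order feature maps (color, luminance,
#' background) heavily; the control-like viewer weights higher-order maps
#' (faces, depth, complexity). These are simulation fixtures for
#' validating the pipeline, not claims about any clinical population.
#'
#' @param features Character vector of available feature labels; weights
#'   are assigned over the intersection with the profile's preferences.
#' @param gaze_noise_deg Jitter SD passed to both profiles.
#' @return Named list with elements `cvi` and `control`.
#' @export
default_group_profiles <- function(features, gaze_noise_deg = 0.02) {
  pick <- function(prefs) {
    w <- prefs[names(prefs) %in% features]
    if (!length(w)) stop("no preferred features present in `features`", call. = FALSE)
    w / sum(w) * 0.8                    # 0.2 uniform exploration
  }
  cvi_pref <- c(red = 1, yellow = 1, luminance = 1, background = 1.5)
  ctl_pref <- c(human_faces = 1.5, depth = 1, complexity = 1)
  list(
    cvi = viewer_profile("cvi_like", pick(cvi_pref),
                         gaze_noise_deg = gaze_noise_deg),
    control = viewer_profile("control_like", pick(ctl_pref),
                             gaze_noise_deg = gaze_noise_deg))
}

# mixture probability over map pixels for one image
mixture_probs <- function(profile, maps) {
  w <- profile$attention_weights
  w <- w[names(w) %in% names(maps)]
  d <- dim(maps[[1]])
  npix <- prod(d)
  p <- matrix(0, d[1], d[2])
  for (f in names(w)) {
    m <- maps[[f]]
    if (!all(dim(m) == d)) stop("maps for one image must share dimensions",
                                call. = FALSE)
    s <- sum(m)
    if (s > 0) p <- p + w[[f]] * unclass_map(m) / s
  }
  rem <- 1 - sum(w)
  p <- p + rem / npix
  tot <- sum(p)
  if (tot <= 0) stop("all-zero attention mixture: no map mass and no uniform remainder",
                     call. = FALSE)
  p / tot
}

sample_targets <- function(prob, n, rect, min_sep_deg = 0, geometry = NULL,
                           prev = NULL) {
  d <- dim(prob)
  idx <- seq_len(length(prob))
  out_x <- numeric(n); out_y <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      k <- sample(idx, 1L, prob = as.vector(prob))
      row <- (k - 1L) %% d[1] + 1L
      col <- (k - 1L) %/% d[1] + 1L
      x <- rect$x + (col - 1L)
      y <- rect$y + (row - 1L)
      if (min_sep_deg <= 0 || is.null(prev)) break
      if (angular_distance_deg(geometry, x, y, prev[1], prev[2]) >= min_sep_deg) break
    }
    out_x[i] <- x; out_y[i] <- y
    prev <- c(x, y)
  }
  tibble::tibble(x = out_x, y = out_y)
}

rtruncnorm_floor <- function(n, mean, sd, floor) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= floor
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Simulate one gaze recording with known ground truth
#'
#' Renders a 500 Hz-style binocular gaze stream for one simulated viewer:
#' per trial, fixation targets are drawn from the viewer's attention
#' mixture over that image's feature maps, fixation durations from the
#' profile's truncated normal, and saccades as minimum-jerk transitions
#' (whose velocity/acceleration peaks scale with amplitude, so multi-degree
#' saccades comfortably exceed the detector's 30 deg/s and 8000 deg/s^2
#' thresholds). The final fixation of each trial is extended to the trial
#' offset so the script tiles the trial exactly. Per-sample Gaussian noise
#' is added independently per eye, so binocular compositing halves its
#' variance as with real recordings.
#'
#' @param profile A [viewer_profile()].
#' @param maps Named list: `maps[[image_id]]` is a named list of
#'   [saliency_map()]s (or raw matrices) keyed by feature label, all sized
#'   like the trial's image rect.
#' @param geometry A [screen_geometry()].
#' @param trials Trial tibble (`image_id,onset_ms,offset_ms,rect_*`).
#' @param sample_rate_hz Sampling rate (500 by default).
#' @param seed RNG seed: identical seeds give identical recordings.
#' @param min_target_sep_deg Optional minimum angular separation between
#'   consecutive fixation targets, enforced by rejection resampling
#'   (0 = unbiased sampling proportional to the mixture; positive values
#'   bias the marginal distribution slightly but guarantee the detector
#'   can separate consecutive fixations).
#' @param participant_id,group_label Metadata for the recording.
#' @return List with `recording` (a [gaze_recording()]) and `script`
#'   (tibble of ground-truth events: `trial_index`, `image_id`, `kind`,
#'   `onset_ms`, `offset_ms`, `duration_ms`, `x_px`, `y_px`).
#' @export
simulate_recording <- function(profile, maps, geometry, trials,
                               sample_rate_hz = 500, seed = 1L,
                               min_target_sep_deg = 0,
                               participant_id = "sim01",
                               group_label = "custom") {
  stopifnot(inherits(profile, "viewer_profile"))
  assert_geometry(geometry)
  trials <- validate_trials(trials, geometry)
  set.seed(as.integer(seed))
  dt <- 1000 / sample_rate_hz
  on_grid <- function(ms) round(ms / dt) * dt

  script <- list()
  sample_chunks <- list()
  ppd <- px_per_deg(geometry)

  for (ti in seq_len(nrow(trials))) {
    tr <- trials[ti, ]
    rect <- as_rect(c(x = tr$rect_x, y = tr$rect_y, w = tr$rect_w, h = tr$rect_h))
    img_maps <- maps[[tr$image_id]]
    if (is.null(img_maps) || !length(img_maps)) {
      stop("no maps supplied for image '", tr$image_id, "'", call. = FALSE)
    }
    prob <- mixture_probs(profile, img_maps)
    sacc_ms <- on_grid(profile$saccade_duration_ms)

    # lay down the ground-truth event sequence
    t <- tr$onset_ms
    prev_target <- NULL
    ev <- list()
    repeat {
      tgt <- sample_targets(prob, 1L, rect, min_target_sep_deg, geometry,
                            prev = prev_target)
      d <- on_grid(rtruncnorm_floor(1, profile$fixation_duration_mean_ms,
                                    profile$fixation_duration_sd_ms,
                                    profile$min_fixation_ms))
      remaining_after <- tr$offset_ms - (t + d)
      if (remaining_after < sacc_ms + profile$min_fixation_ms) {
        d <- tr$offset_ms - t            # extend final fixation to offset
        ev[[length(ev) + 1L]] <- tibble::tibble(
          kind = "fixation", onset_ms = t, offset_ms = t + d,
          x_px = tgt$x, y_px = tgt$y)
        break
      }
      ev[[length(ev) + 1L]] <- tibble::tibble(
        kind = "fixation", onset_ms = t, offset_ms = t + d,
        x_px = tgt$x, y_px = tgt$y)
      ev[[length(ev) + 1L]] <- tibble::tibble(
        kind = "saccade", onset_ms = t + d, offset_ms = t + d + sacc_ms,
        x_px = NA_real_, y_px = NA_real_)
      t <- t + d + sacc_ms
      prev_target <- c(tgt$x, tgt$y)
    }
    ev <- dplyr::bind_rows(ev)
    ev$trial_index <- ti
    ev$image_id <- tr$image_id
    script[[ti]] <- ev

    # render samples on the grid [onset, offset)
    ts <- seq(tr$onset_ms, tr$offset_ms - dt / 2, by = dt)
    x <- numeric(length(ts)); y <- numeric(length(ts))
    fix_rows <- which(ev$kind == "fixation")
    for (k in seq_len(nrow(ev))) {
      inwin <- ts >= ev$onset_ms[k] & ts < ev$offset_ms[k]
      if (!any(inwin)) next
      if (ev$kind[k] == "fixation") {
        x[inwin] <- ev$x_px[k]; y[inwin] <- ev$y_px[k]
      } else {
        from <- ev[k - 1L, ]; to <- ev[k + 1L, ]
        tau <- (ts[inwin] - ev$onset_ms[k]) / (ev$offset_ms[k] - ev$onset_ms[k])
        s <- min_jerk(tau)
        x[inwin] <- from$x_px + s * (to$x_px - from$x_px)
        y[inwin] <- from$y_px + s * (to$y_px - from$y_px)
      }
    }
    noise_px_x <- profile$gaze_noise_deg * ppd[["x"]]
    noise_px_y <- profile$gaze_noise_deg * ppd[["y"]]
    nz <- function(sdv) if (sdv > 0) stats::rnorm(length(ts), 0, sdv) else 0
    sample_chunks[[ti]] <- tibble::tibble(
      t_ms = ts,
      lx = x + nz(noise_px_x), ly = y + nz(noise_px_y),
      rx = x + nz(noise_px_x), ry = y + nz(noise_px_y),
      lvalid = 1L, rvalid = 1L)
  }

  samples <- dplyr::bind_rows(sample_chunks)
  script <- dplyr::bind_rows(script)
  script$duration_ms <- script$offset_ms - script$onset_ms
  script <- script[, c("trial_index", "image_id", "kind", "onset_ms",
                       "offset_ms", "duration_ms", "x_px", "y_px")]
  rec <- gaze_recording(samples, geometry, sample_rate_hz, trials = trials,
                        participant_id = participant_id,
                        group_label = group_label)
  list(recording = rec, script = script)
}

#' Simulate a two-group cohort
#'
#' Draws per-participant seeds deterministically from a master seed and
#' simulates `n_per_group` recordings per group from the supplied
#' profiles. Identical master seeds reproduce the cohort exactly.
#'
#' @param n_per_group Participants per group (>= 1).
#' @param profiles Named list of [viewer_profile()]s, one per group label.
#' @param maps,geometry,trials,sample_rate_hz,min_target_sep_deg Passed to
#'   [simulate_recording()].
#' @param seed Master seed.
#' @return List with `recordings` (list of [gaze_recording()]), `scripts`
#'   (list of script tibbles) and `manifest` (tibble
#'   `participant_id, group_label, seed`).
#' @export
simulate_cohort <- function(n_per_group, profiles, maps, geometry, trials,
                            sample_rate_hz = 500, seed = 1L,
                            min_target_sep_deg = 0) {
  stopifnot(n_per_group >= 1, length(profiles) >= 1, !is.null(names(profiles)))
  set.seed(as.integer(seed))
  groups <- rep(names(profiles), each = n_per_group)
  n_total <- length(groups)
  seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  ids <- sprintf("sim%03d", seq_len(n_total))
  out <- purrr::pmap(list(ids, groups, seeds), function(id, grp, sd) {
    simulate_recording(profiles[[grp]], maps, geometry, trials,
                       sample_rate_hz, seed = sd,
                       min_target_sep_deg = min_target_sep_deg,
                       participant_id = id, group_label = grp)
  })
  list(recordings = purrr::map(out, "recording"),
       scripts = purrr::map(out, "script"),
       manifest = tibble::tibble(participant_id = ids, group_label = groups,
                                 seed = seeds))
}

#' Write a complete simulated study to disk
#'
#' Generates a ready-to-analyze miniature study: a two-group simulated
#' cohort, its gaze and trial CSVs, feature-map PNGs with a manifest, a
#' participants table and the ground-truth script — everything
#' [run_pipeline()] needs, plus the script for validation. The default
#' stimulus set is two images with a two-blob "human_faces" map and a
#' left-half field map; the default profiles mirror the anticipated group
#' contrast (see [default_group_profiles()]).
#'
#' @param dir Output directory (created if needed).
#' @param n_per_group Participants per group.
#' @param geometry A [screen_geometry()].
#' @param n_trials,trial_ms Stimulus presentation schedule.
#' @param gaze_noise_deg Per-sample jitter SD, degrees.
#' @param seed Master seed.
#' @param min_target_sep_deg Passed to [simulate_recording()].
#' @return Invisibly, the path to a pipeline config YAML inside `dir`.
#' @export
write_simulated_study <- function(dir, n_per_group = 2,
                                  geometry = screen_geometry(1920, 1080,
                                                             53.1, 29.9, 60),
                                  n_trials = 2, trial_ms = 5000,
                                  gaze_noise_deg = 0.02, seed = 1L,
                                  min_target_sep_deg = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trials <- tibble::tibble(
    image_id = paste0("img", seq_len(n_trials)),
    onset_ms = (seq_len(n_trials) - 1) * trial_ms,
    offset_ms = seq_len(n_trials) * trial_ms,
    rect_x = 560, rect_y = 140, rect_w = 800, rect_h = 800)
  blob <- smooth_and_normalize(
    make_feature_map("blob", 800, 800,
                     centers = data.frame(x = c(150, 600), y = c(200, 550),
                                          sigma = 60)),
    sigma_px = 0, feature_label = "human_faces")
  left <- smooth_and_normalize(
    make_feature_map("field_half", 800, 800, side = "left"),
    sigma_px = 2, feature_label = "field_left")
  per_image <- list(human_faces = blob, field_left = left)
  maps <- stats::setNames(rep(list(per_image), n_trials), trials$image_id)

  profs <- list(
    cvi = viewer_profile("cvi_like", c(field_left = 0.7),
                         gaze_noise_deg = gaze_noise_deg),
    control = viewer_profile("control_like", c(human_faces = 0.7),
                             gaze_noise_deg = gaze_noise_deg))
  coh <- simulate_cohort(n_per_group, profs, maps, geometry, trials,
                         seed = seed,
                         min_target_sep_deg = min_target_sep_deg)

  write_map_png(blob, file.path(dir, "human_faces.png"))
  write_map_png(left, file.path(dir, "field_left.png"))
  readr::write_csv(tibble::tibble(
    image_id = rep(trials$image_id, each = 2),
    feature_label = rep(c("human_faces", "field_left"), n_trials),
    map_path = rep(c("human_faces.png", "field_left.png"), n_trials)),
    file.path(dir, "maps.csv"), progress = FALSE)
  write_trials_csv(trials, file.path(dir, "trials.csv"))

  parts <- coh$manifest
  parts$gaze_csv <- paste0(parts$participant_id, "_gaze.csv")
  parts$trials_csv <- "trials.csv"
  purrr::walk2(coh$recordings, parts$gaze_csv, function(r, f) {
    write_gaze_csv(r, file.path(dir, f))
  })
  readr::write_csv(parts[c("participant_id", "group_label", "gaze_csv",
                           "trials_csv")],
                   file.path(dir, "participants.csv"), progress = FALSE)
  readr::write_csv(dplyr::bind_rows(purrr::map2(
    coh$scripts, parts$participant_id,
    function(s, id) dplyr::mutate(s, participant_id = id))),
    file.path(dir, "ground_truth_script.csv"), progress = FALSE)

  cfg <- list(
    geometry = list(width_px = geometry$width_px,
                    height_px = geometry$height_px,
                    width_cm = geometry$width_cm,
                    height_cm = geometry$height_cm,
                    distance_cm = geometry$distance_cm),
    sample_rate_hz = 500,
    participants_csv = "participants.csv",
    maps_manifest_csv = "maps.csv",
    output_dir = file.path(dir, "results"),
    seed = as.integer(seed))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
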