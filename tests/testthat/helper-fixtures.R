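# Shared fixtures: a 24-inch 16:9 monitor viewed at 60 cm, small stimulus
# rects, and canned synthetic maps. All fixtures are built in code.

fixture_geometry <- function() {
  screen_geometry(1920, 1080, 53.1, 29.9, 60)
}

fixture_trials <- function(n = 2, trial_ms = 5000, rect = c(560, 140, 800, 800)) {
  tibble::tibble(
    image_id = paste0("img", seq_len(n)),
    onset_ms = (seq_len(n) - 1) * trial_ms,
    offset_ms = seq_len(n) * trial_ms,
    rect_x = rect[1], rect_y = rect[2], rect_w = rect[3], rect_h = rect[4])
}

# two well-separated Gaussian blobs; raw in [0, 1]
fixture_blob_raw <- function(size = 800) {
  make_feature_map("blob", size, size,
                   centers = data.frame(x = c(150, 600), y = c(200, 550),
                                        sigma = 60))
}

fixture_maps <- function(trials, size = 800) {
  blob <- smooth_and_normalize(fixture_blob_raw(size), sigma_px = 0,
                               feature_label = "human_faces")
  left <- smooth_and_normalize(
    make_feature_map("field_half", size, size, side = "left"),
    sigma_px = 2, feature_label = "field_left")
  per_image <- list(human_faces = blob, field_left = left)
  maps <- stats::setNames(rep(list(per_image), nrow(trials)), trials$image_id)
  manifest <- tibble::tibble(
    image_id = rep(trials$image_id, each = 2),
    feature_label = rep(c("human_faces", "field_left"), nrow(trials)),
    map = rep(list(blob, left), nrow(trials)))
  list(maps = maps, manifest = manifest, blob = blob, left = left)
}

# a constant-position composite stream at 500 Hz
constant_stream <- function(x, y, from_ms, to_ms, dt = 2) {
  t <- seq(from_ms, to_ms, by = dt)
  tibble::tibble(t_ms = t, x_px = x, y_px = y, valid = TRUE)
}

# mean map intensity under sampling proportional to intensity
intensity_weighted_mean <- function(map) {
  m <- as.numeric(unclass(map))
  sum(m^2) / sum(m)
}
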