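fake_fixation <- function(x, y, onset = 0, dur = 200) {
  tibble::tibble(type = "fixation", onset_ms = onset, offset_ms = onset + dur,
                 duration_ms = dur, x_px = x, y_px = y,
                 x_deg = NA_real_, y_deg = NA_real_,
                 dispersion_deg = 0.05, amplitude_deg = NA_real_,
                 peak_vel_deg_s = NA_real_, peak_acc_deg_s2 = NA_real_)
}

test_that("the 20% out-of-image rule keeps and discards per axis", {
  rect <- c(x = 0, y = 0, w = 800, h = 600)
  center <- fake_fixation(400, 300)
  expect_equal(nrow(filter_fixations(center, rect)), 1)
  expect_false(filter_fixations(center, rect)$off_image)

  # 21.25% beyond the left edge (x = -170 on an 800 px image): discarded
  expect_equal(nrow(filter_fixations(fake_fixation(-170, 300), rect)), 0)
  # 12.5% beyond (x = -100): kept, flagged off-image
  kept <- filter_fixations(fake_fixation(-100, 300), rect)
  expect_equal(nrow(kept), 1)
  expect_true(kept$off_image)
  # vertical margin uses the image height (20% of 600 = 120)
  expect_equal(nrow(filter_fixations(fake_fixation(400, 721), rect)), 0)
  expect_equal(nrow(filter_fixations(fake_fixation(400, 719), rect)), 1)

  expect_error(filter_fixations(center, c(x = 0, y = 0, w = 0, h = 600)),
               "degenerate")
  expect_error(filter_fixations(center, rect, margin_frac = 1.2), "margin_frac")
})

test_that("fixation_value looks up the nearest map pixel, clamps in-margin overshoot", {
  intens <- matrix(0, 10, 10)
  intens[3, 7] <- 255          # row 3 (y = 2), col 7 (x = 6)
  intens[1, 1] <- 17
  map <- saliency_map(intens, "unit", normalized = TRUE)
  rect <- c(x = 100, y = 50, w = 10, h = 10)

  expect_equal(fixation_value(106, 52, map, rect), 255)
  expect_equal(fixation_value(100, 50, map, rect), 17)
  expect_equal(fixation_value(106.4, 52.4, map, rect), 255)  # nearest pixel
  # off-image within margin: clamped to the boundary pixel
  expect_equal(fixation_value(97, 50, map, rect), 17)

  const <- saliency_map(matrix(5, 4, 4), "flat", normalized = TRUE,
                        constant = TRUE)
  expect_error(fixation_value(1, 1, const, rect), "constant")

  # degenerate uniform-255 map with the constant guard overridden:
  # every fixation scores 255
  uni <- saliency_map(matrix(255, 4, 4), "uniform", normalized = TRUE,
                      constant = FALSE)
  expect_equal(fixation_value(c(100, 104, 109), c(50, 55, 59), uni, rect),
               c(255, 255, 255))
})

test_that("sampling proportional to intensity gives the intensity-weighted mean", {
  # two-pixel map {200, 100}: long-run mean = (200^2 + 100^2) / 300
  map <- saliency_map(matrix(c(200, 100), 1, 2), "two", normalized = TRUE)
  rect <- c(x = 0, y = 0, w = 2, h = 1)
  set.seed(13)
  n <- 20000
  xs <- sample(c(0, 1), n, replace = TRUE, prob = c(200, 100))
  vals <- fixation_value(xs, rep(0, n), map, rect)
  expect_equal(mean(vals), (200^2 + 100^2) / 300, tolerance = 0.01)
})

test_that("score_session averages per image then per participant and drops empty trials", {
  trials <- fixture_trials(2, trial_ms = 1000, rect = c(0, 0, 10, 10))
  intens <- matrix(100, 10, 10); intens[1, 1] <- 0; intens[10, 10] <- 255
  intens[5, 5] <- 200
  map <- saliency_map(intens, "f", normalized = TRUE)
  manifest <- tibble::tibble(image_id = c("img1", "img2"),
                             feature_label = "f", map = list(map, map))
  # trial 1: two fixations scoring 100 and 200 -> image mean 150
  # trial 2: one fixation scoring 250 is discarded (far out of range),
  #          one scoring 255 remains -> image mean 255... use 255 pixel
  ev <- dplyr::bind_rows(
    fake_fixation(3, 3, onset = 100),
    fake_fixation(4, 4, onset = 500),   # row5,col5 -> 200
    fake_fixation(9, 9, onset = 1100))
  sc <- score_session(NULL, ev, manifest, trials = trials,
                      participant_id = "p1", group_label = "cvi")
  expect_equal(sort(sc$records$value), c(100, 200, 255))
  expect_equal(sc$summaries$overall_mean, mean(c(150, 255)))
  expect_equal(sc$summaries$n_trials, 2)
  expect_equal(sc$summaries$n_fixations, 3)

  # a trial whose only fixation is discarded vanishes from the averages
  ev2 <- dplyr::bind_rows(
    fake_fixation(3, 3, onset = 100),
    fake_fixation(4, 4, onset = 500),
    fake_fixation(500, 500, onset = 1100))   # far outside: discarded
  sc2 <- score_session(NULL, ev2, manifest, trials = trials,
                       participant_id = "p1", group_label = "cvi")
  expect_equal(sc2$summaries$overall_mean, 150)
  expect_equal(sc2$summaries$n_trials, 1)

  # manifest gap: the (image, feature) pair is skipped with a warning
  man1 <- manifest[1, ]
  expect_warning(
    sc3 <- score_session(NULL, ev, man1, trials = trials,
                         participant_id = "p1", group_label = "cvi"),
    "img2")
  expect_equal(sc3$summaries$n_trials, 1)

  # emitted values are integers in 0..255 drawn from the map
  expect_true(all(sc$records$value %in% as.numeric(intens)))
})

test_that("fixations are assigned to trials by temporal midpoint", {
  trials <- fixture_trials(2, trial_ms = 1000, rect = c(0, 0, 10, 10))
  map <- saliency_map(matrix(7, 10, 10) + diag(10), "f", normalized = TRUE)
  manifest <- tibble::tibble(image_id = c("img1", "img2"),
                             feature_label = "f",
                             map = list(map, map))
  straddle <- fake_fixation(5, 5, onset = 950, dur = 200)  # midpoint 1050
  sc <- score_session(NULL, straddle, manifest, trials = trials,
                      participant_id = "p", group_label = "g")
  expect_equal(unique(sc$records$image_id), "img2")
})
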