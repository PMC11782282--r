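test_that("feature-map generators produce the advertised shapes", {
  left <- make_feature_map("field_half", 8, 6, side = "left")
  expect_true(all(left[, 1:3] == 1))
  expect_true(all(left[, 5:8] == 0))
  upper <- make_feature_map("field_half", 8, 6, side = "upper")
  expect_true(all(upper[1:2, ] == 1) && all(upper[4:6, ] == 0))
  cen <- make_feature_map("field_half", 21, 21, side = "center")
  per <- make_feature_map("field_half", 21, 21, side = "periphery")
  expect_equal(cen + per, matrix(1, 21, 21))   # exact partition

  blob <- make_feature_map("blob", 41, 41,
                           centers = data.frame(x = 20, y = 20, sigma = 5))
  expect_equal(which(blob == max(blob)), 21 + 20 * 41)  # argmax at center
  bg <- make_feature_map("background", 41, 41,
                         centers = data.frame(x = 20, y = 20, sigma = 5))
  expect_equal(bg, 1 - blob)

  expect_error(make_feature_map("blob", 10, 10), "centers")
  expect_error(make_feature_map("field_half", 10, 10, side = "diagonal"),
               "unknown field side")
})

test_that("a 5 cpd synthetic grating is consistent with the spectrum module", {
  geom <- fixture_geometry()
  rect <- c(x = 560, y = 140, w = 256, h = 256)
  g <- make_feature_map("grating", 256, 256, cpd = 5, geometry = geom,
                        image_rect = rect)
  expect_equal(
    high_freq_energy_fraction(g, geom, rect, 3)$energy_fraction_above, 1.0,
    tolerance = 1e-9)
})

test_that("viewer profiles validate their invariants", {
  expect_error(viewer_profile("x", c(0.5, 0.5)), "named")
  expect_error(viewer_profile("x", c(a = -0.1)), ">= 0")
  expect_error(viewer_profile("x", c(a = 0.7, b = 0.6)), "at most 1")
  expect_error(viewer_profile("x", c(a = 0.5), fixation_duration_mean_ms = 50,
                              min_fixation_ms = 80), "floor")
  p <- viewer_profile("ok", c(human_faces = 0.9))
  expect_s3_class(p, "viewer_profile")
})

test_that("simulation is deterministic: same seed, byte-identical CSV output", {
  geom <- fixture_geometry()
  trials <- fixture_trials(1, trial_ms = 3000)
  fm <- fixture_maps(trials)
  prof <- viewer_profile("t", c(human_faces = 0.8), gaze_noise_deg = 0.02)
  s1 <- simulate_recording(prof, fm$maps, geom, trials, seed = 99)
  s2 <- simulate_recording(prof, fm$maps, geom, trials, seed = 99)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_gaze_csv(s1$recording, f1)
  write_gaze_csv(s2$recording, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(s1$script, s2$script)

  s3 <- simulate_recording(prof, fm$maps, geom, trials, seed = 100)
  expect_false(identical(s1$script$x_px, s3$script$x_px))
})

test_that("the script tiles each trial and fixation counts follow the renewal expectation", {
  geom <- fixture_geometry()
  trials <- fixture_trials(1, trial_ms = 10000)
  fm <- fixture_maps(trials)
  prof <- viewer_profile("t", c(human_faces = 0.5),
                         fixation_duration_mean_ms = 250,
                         fixation_duration_sd_ms = 50,
                         saccade_duration_ms = 50)
  counts <- vapply(1:5, function(sd) {
    s <- simulate_recording(prof, fm$maps, geom, trials, seed = sd)
    sc <- s$script
    # intervals tile the trial without overlap
    expect_equal(sc$onset_ms[1], 0)
    expect_equal(sc$offset_ms[nrow(sc)], 10000)
    expect_equal(sc$onset_ms[-1], sc$offset_ms[-nrow(sc)])
    sum(sc$kind == "fixation")
  }, numeric(1))
  # renewal expectation: 10000 / (250 + 50) = 33.3 per trial
  expect_gt(mean(counts), 33.3 - 3)
  expect_lt(mean(counts), 33.3 + 3)
})

test_that("a one-hot map with zero exploration pins every fixation to that pixel", {
  geom <- fixture_geometry()
  trials <- fixture_trials(1, trial_ms = 2000, rect = c(560, 140, 50, 50))
  hot <- matrix(0, 50, 50); hot[20, 30] <- 255   # x = 29, y = 19 in map coords
  maps <- list(img1 = list(f = saliency_map(hot, "f", normalized = TRUE)))
  prof <- viewer_profile("t", c(f = 1))
  s <- simulate_recording(prof, maps, geom, trials, seed = 5)
  fx <- s$script[s$script$kind == "fixation", ]
  expect_true(all(fx$x_px == 560 + 29))
  expect_true(all(fx$y_px == 140 + 19))

  # all-zero mixture is an error
  zero <- list(img1 = list(f = saliency_map(matrix(0, 50, 50), "f",
                                            normalized = TRUE)))
  expect_error(simulate_recording(prof, zero, geom, trials, seed = 5),
               "all-zero")
})

test_that("higher attention weight on a map yields higher mean saliency on it", {
  geom <- fixture_geometry()
  trials <- fixture_trials(1, trial_ms = 4000)
  fm <- fixture_maps(trials)
  profA <- viewer_profile("A", c(human_faces = 0.9))
  profB <- viewer_profile("B", c(human_faces = 0.1))
  wins <- vapply(1:40, function(sd) {
    sA <- simulate_recording(profA, fm$maps, geom, trials, seed = sd)
    sB <- simulate_recording(profB, fm$maps, geom, trials, seed = 10000 + sd)
    rect <- c(x = 560, y = 140, w = 800, h = 800)
    fA <- sA$script[sA$script$kind == "fixation", ]
    fB <- sB$script[sB$script$kind == "fixation", ]
    mean(fixation_value(fA$x_px, fA$y_px, fm$blob, rect)) >
      mean(fixation_value(fB$x_px, fB$y_px, fm$blob, rect))
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("cohort simulation is reproducible and labels groups correctly", {
  geom <- fixture_geometry()
  trials <- fixture_trials(1, trial_ms = 1500)
  fm <- fixture_maps(trials)
  profs <- list(cvi = viewer_profile("cvi_like", c(field_left = 0.6)),
                control = viewer_profile("control_like", c(human_faces = 0.6)))
  c1 <- simulate_cohort(1, profs, fm$maps, geom, trials, seed = 7)
  expect_equal(length(c1$recordings), 2)
  expect_equal(c1$manifest$group_label, c("cvi", "control"))
  expect_equal(length(unique(c1$manifest$participant_id)), 2)

  c2 <- simulate_cohort(1, profs, fm$maps, geom, trials, seed = 7)
  expect_identical(c1$manifest, c2$manifest)
  expect_equal(c1$recordings[[1]]$samples, c2$recordings[[1]]$samples)
})
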