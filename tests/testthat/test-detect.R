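test_that("median denoise removes isolated spikes and preserves constants and ramps", {
  s <- constant_stream(500, 400, 0, 200)
  expect_equal(heuristic_denoise(s, 3), s)          # constants unchanged

  spiked <- s; spiked$x_px[50] <- 510                # one-sample +10 px spike
  den <- heuristic_denoise(spiked, 3)
  expect_equal(den$x_px, s$x_px)                     # spike removed exactly

  ramp <- s; ramp$x_px <- seq(100, by = 1, length.out = nrow(s))
  den2 <- heuristic_denoise(ramp, 3)
  expect_equal(den2$x_px[2:(nrow(s) - 1)], ramp$x_px[2:(nrow(s) - 1)])

  expect_error(heuristic_denoise(s, 4), "odd")

  # invalid samples pass through untouched and do not pollute the window
  gap <- spiked; gap$valid[60] <- FALSE; gap$x_px[60] <- 9999
  deng <- heuristic_denoise(gap, 3)
  expect_equal(deng$x_px[60], 9999)
  expect_equal(deng$x_px[-c(50, 60)], s$x_px[-c(50, 60)])
})

test_that("kinematics: central differences recover imposed velocities", {
  geom <- fixture_geometry()
  # constant position: zero velocity and acceleration everywhere
  kc <- compute_kinematics(constant_stream(900, 500, 0, 100), geom, 500)
  expect_true(all(kc$vel_deg_s == 0))
  expect_true(all(kc$acc_deg_s2 == 0))

  # two samples 2 ms apart displaced 0.2 deg: one-sided velocity 100 deg/s
  ctr <- deg_to_px(geom, 0, 0)
  p2 <- deg_to_px(geom, 0.2, 0)
  s2 <- tibble::tibble(t_ms = c(0, 2), x_px = c(ctr$x_px, p2$x_px),
                       y_px = ctr$y_px, valid = TRUE)
  k2 <- compute_kinematics(s2, geom, 500)
  expect_equal(k2$vel_deg_s, c(100, 100), tolerance = 1e-9)

  # constant-velocity drift: acceleration exactly 0 at interior samples
  degs <- seq(0, 2, by = 0.02)
  px <- deg_to_px(geom, degs, degs * 0)
  sd_ <- tibble::tibble(t_ms = seq_along(degs) * 2, x_px = px$x_px,
                        y_px = px$y_px, valid = TRUE)
  kd <- compute_kinematics(sd_, geom, 500)
  inner <- 2:(nrow(kd) - 1)
  expect_lt(max(abs(kd$acc_deg_s2[inner])), 1e-6)
})

test_that("fixation detection honors the dispersion and duration rule", {
  geom <- fixture_geometry()
  p <- detection_params()

  ev <- detect_events(constant_stream(900, 500, 0, 200), geom, p, 500)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "fixation")
  expect_equal(ev$duration_ms, 200)
  expect_equal(ev$x_px, 900)
  expect_equal(ev$y_px, 500)

  # 99 ms of samples is below the 100 ms minimum: nothing emitted
  ev99 <- detect_events(constant_stream(900, 500, 0, 98), geom, p, 500)
  expect_equal(nrow(ev99), 0)

  empty <- tibble::tibble(t_ms = numeric(0), x_px = numeric(0),
                          y_px = numeric(0), valid = logical(0))
  expect_equal(nrow(detect_events(empty, geom, p)), 0)
})

test_that("a ballistic 5-degree transition yields two fixations and one saccade", {
  geom <- fixture_geometry()
  p <- detection_params()
  a <- deg_to_px(geom, -2.5, 0)
  b <- deg_to_px(geom, 2.5, 0)
  minjerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  t <- seq(0, 630, by = 2)
  x <- numeric(length(t))
  x[t < 300] <- a$x_px
  tr <- t >= 300 & t < 330
  x[tr] <- a$x_px + minjerk((t[tr] - 300) / 30) * (b$x_px - a$x_px)
  x[t >= 330] <- b$x_px
  st <- tibble::tibble(t_ms = t, x_px = x, y_px = a$y_px, valid = TRUE)

  ev <- detect_events(st, geom, p, 500)
  expect_equal(sum(ev$type == "fixation"), 2)
  expect_equal(sum(ev$type == "saccade"), 1)
  sac <- ev[ev$type == "saccade", ]
  expect_equal(sac$amplitude_deg, 5, tolerance = 0.05)
  expect_gt(sac$peak_vel_deg_s, 30)
  expect_gt(sac$peak_acc_deg_s2, 8000)
  fx <- ev[ev$type == "fixation", ]
  expect_equal(fx$x_px, c(a$x_px, b$x_px), tolerance = 0.5)

  # events sorted, non-overlapping, and fixations satisfy their invariants
  expect_true(all(diff(ev$onset_ms) > 0))
  expect_true(all(ev$offset_ms[-nrow(ev)] <= ev$onset_ms[-1]))
  expect_true(all(fx$duration_ms >= p$min_fix_duration_ms))
  expect_true(all(fx$dispersion_deg <= p$dispersion_deg))
})

test_that("invalidity gaps break events", {
  geom <- fixture_geometry()
  s <- constant_stream(900, 500, 0, 400)
  s$valid[s$t_ms >= 196 & s$t_ms <= 204] <- FALSE   # 5-sample blink
  ev <- detect_events(s, geom, detection_params(), 500)
  expect_equal(nrow(ev), 2)                          # split, both long enough
  expect_true(all(ev$type == "fixation"))
  expect_true(all(ev$duration_ms < 400))
})

test_that("events CSV writer/reader round-trips the event table", {
  geom <- fixture_geometry()
  ev <- detect_events(constant_stream(900, 500, 0, 200), geom,
                      detection_params(), 500)
  f <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(ev, f)
  back <- read_events_csv(f, geom)
  expect_equal(back$type, ev$type)
  expect_equal(back$x_px, ev$x_px)
  expect_equal(back$duration_ms, ev$duration_ms)
  expect_equal(back$x_deg, ev$x_deg, tolerance = 1e-9)
})
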