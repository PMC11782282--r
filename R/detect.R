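#' Oculomotor event-detection parameters
#'
#' Thresholds for fixation and saccade detection. Defaults are the standard
#' video-oculography settings for cognitive research: a fixation is a period
#' of gaze stable within 0.1 degree of its centroid lasting at least 100 ms;
#' a saccade is a ballistic movement whose speed exceeds 30 deg/s and whose
#' acceleration exceeds 8000 deg/s^2 over an amplitude greater than 0.1
#' degree.
#'
#' @param dispersion_deg Maximum distance of any member sample from the
#'   fixation centroid, degrees.
#' @param min_fix_duration_ms Minimum fixation duration, ms.
#' @param saccade_velocity_deg_s Peak-speed threshold, deg/s.
#' @param saccade_accel_deg_s2 Peak-acceleration threshold, deg/s^2.
#' @param saccade_amplitude_deg Minimum saccade amplitude, degrees.
#' @param denoise_window_samples Odd window (samples) for the median
#'   denoising filter; see [heuristic_denoise()].
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(dispersion_deg = 0.1,
                             min_fix_duration_ms = 100,
                             saccade_velocity_deg_s = 30,
                             saccade_accel_deg_s2 = 8000,
                             saccade_amplitude_deg = 0.1,
                             denoise_window_samples = 3L) {
  p <- list(dispersion_deg = dispersion_deg,
            min_fix_duration_ms = min_fix_duration_ms,
            saccade_velocity_deg_s = saccade_velocity_deg_s,
            saccade_accel_deg_s2 = saccade_accel_deg_s2,
            saccade_amplitude_deg = saccade_amplitude_deg,
            denoise_window_samples = as.integer(denoise_window_samples))
  if (any(unlist(p) <= 0)) stop("all detection parameters must be strictly positive",
                                call. = FALSE)
  structure(p, class = "detection_params")
}

#' Median-filter denoising of a composite gaze stream
#'
#' A documented, reproducible replacement for the unpublished vendor
#' "heuristic filter": a sliding per-axis median over the valid samples.
#' Invalid samples pass through unchanged and do not contribute to any
#' window; near the ends of each valid stretch the window shrinks
#' symmetrically. Output length equals input length. A 3-sample median
#' removes isolated one-sample spikes exactly while leaving monotone ramps
#' untouched.
#'
#' @param stream Composite gaze tibble (`t_ms`, `x_px`, `y_px`, `valid`),
#'   e.g. from [binocular_composite()].
#' @param window Odd window length in samples (1 = no-op).
#' @return The stream with `x_px`, `y_px` median-filtered.
#' @export
heuristic_denoise <- function(stream, window = 3L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("denoise window must be an odd positive sample count", call. = FALSE)
  }
  stream <- tibble::as_tibble(stream)
  idx <- which(stream$valid)
  if (window == 1L || length(idx) < 2L) return(stream)
  k <- min(window, if (length(idx) %% 2L == 1L) length(idx) else length(idx) - 1L)
  stream$x_px[idx] <- stats::runmed(stream$x_px[idx], k, endrule = "median")
  stream$y_px[idx] <- stats::runmed(stream$y_px[idx], k, endrule = "median")
  stream
}

# Split a composite stream into differentiable blocks: consecutive valid
# samples with inter-sample gaps no longer than max_gap_ms. Returns a list
# of integer index vectors into the stream.
stream_blocks <- function(stream, max_gap_ms) {
  idx <- which(stream$valid & is.finite(stream$x_px) & is.finite(stream$y_px))
  if (!length(idx)) return(list())
  brk <- c(0L, which(diff(stream$t_ms[idx]) > max_gap_ms), length(idx))
  lapply(seq_len(length(brk) - 1L),
         function(i) idx[(brk[i] + 1L):brk[i + 1L]])
}

central_diff <- function(v, t) {
  n <- length(v)
  if (n < 2L) return(rep(NA_real_, n))
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / (t[2] - t[1])
  d[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    d[i] <- (v[i + 1] - v[i - 1]) / (t[i + 1] - t[i - 1])
  }
  d
}

#' Per-sample gaze kinematics in degree space
#'
#' Converts the composite stream to degrees of visual angle and estimates
#' per-sample speed (deg/s) and its rate of change (deg/s^2) by central
#' differences, with one-sided differences at stretch endpoints. Invalid
#' samples and gaps longer than `max_gap_intervals` nominal inter-sample
#' intervals break the differentiation windows; kinematics there are `NA`.
#'
#' @param stream Composite gaze tibble (`t_ms`, `x_px`, `y_px`, `valid`).
#' @param geometry A [screen_geometry()].
#' @param sample_rate_hz Nominal rate, used only to size the gap rule.
#' @param max_gap_intervals Longest bridgeable gap, in units of the nominal
#'   inter-sample interval.
#' @return The stream with added columns `x_deg`, `y_deg`, `vel_deg_s`,
#'   `acc_deg_s2`.
#' @export
compute_kinematics <- function(stream, geometry, sample_rate_hz = 500,
                               max_gap_intervals = 2) {
  assert_geometry(geometry)
  stream <- tibble::as_tibble(stream)
  deg <- px_to_deg(geometry, stream$x_px, stream$y_px)
  stream$x_deg <- deg$x_deg
  stream$y_deg <- deg$y_deg
  stream$vel_deg_s <- NA_real_
  stream$acc_deg_s2 <- NA_real_
  max_gap_ms <- max_gap_intervals * 1000 / sample_rate_hz
  for (blk in stream_blocks(stream, max_gap_ms)) {
    if (length(blk) < 2L) next
    ts <- stream$t_ms[blk] / 1000
    vx <- central_diff(stream$x_deg[blk], ts)
    vy <- central_diff(stream$y_deg[blk], ts)
    sp <- sqrt(vx^2 + vy^2)
    stream$vel_deg_s[blk] <- sp
    if (length(blk) >= 3L) stream$acc_deg_s2[blk] <- central_diff(sp, ts)
  }
  stream
}

# Greedy left-to-right dispersion carving of one candidate segment.
# Returns a list of index ranges (into `rows`) that satisfy the dispersion
# criterion; duration filtering happens in the caller.
idt_carve <- function(x_deg, y_deg, dispersion_deg) {
  n <- length(x_deg)
  out <- list()
  start <- 1L
  while (start <= n) {
    end <- start
    while (end < n) {
      j <- start:(end + 1L)
      cx <- mean(x_deg[j]); cy <- mean(y_deg[j])
      disp <- max(sqrt((x_deg[j] - cx)^2 + (y_deg[j] - cy)^2))
      if (disp > dispersion_deg) break
      end <- end + 1L
    }
    out[[length(out) + 1L]] <- c(start, end)
    start <- end + 1L
  }
  out
}

#' Detect fixations and saccades from a composite gaze stream
#'
#' Two-stage detection honoring both the kinematic saccade definition and
#' the dispersion/duration fixation definition. Stage 1 marks candidate
#' saccadic samples where speed exceeds the velocity threshold or
#' |acceleration| exceeds the acceleration threshold; a maximal run of such
#' samples is kept as a saccade only if its peak speed, peak |acceleration|
#' and amplitude all exceed their thresholds (a smooth saccade's
#' acceleration changes sign mid-flight, so the run rule is a disjunction
#' while the event-level criteria are conjunctive on the peaks). Stage 2
#' carves the inter-saccade segments into fixations by greedy left-to-right
#' dispersion clustering (I-DT style): a window grows while every member
#' stays within `dispersion_deg` of the running centroid, closes when the
#' next sample would violate it, and is emitted as a fixation when its
#' member-sample span reaches `min_fix_duration_ms`.
#'
#' Events never span invalidity gaps longer than two nominal inter-sample
#' intervals; emitted events are sorted by onset and non-overlapping.
#'
#' @param stream Composite gaze tibble; denoise first with
#'   [heuristic_denoise()] if desired.
#' @param geometry A [screen_geometry()].
#' @param params A [detection_params()].
#' @param sample_rate_hz Nominal rate for the gap rule.
#' @return A tibble of class `gaze_events` with columns `type`
#'   (`"fixation"`/`"saccade"`), `onset_ms`, `offset_ms`, `duration_ms`,
#'   `x_px`, `y_px` (fixation centroid), `x_deg`, `y_deg`,
#'   `dispersion_deg`, `amplitude_deg`, `peak_vel_deg_s`,
#'   `peak_acc_deg_s2`.
#' @export
detect_events <- function(stream, geometry, params = detection_params(),
                          sample_rate_hz = 500) {
  assert_geometry(geometry)
  stopifnot(inherits(params, "detection_params"))
  stream <- tibble::as_tibble(stream)
  empty <- empty_events()
  if (!nrow(stream)) return(empty)
  kin <- compute_kinematics(stream, geometry, sample_rate_hz)
  max_gap_ms <- 2 * 1000 / sample_rate_hz

  events <- list()
  for (blk in stream_blocks(kin, max_gap_ms)) {
    t <- kin$t_ms[blk]
    xd <- kin$x_deg[blk]; yd <- kin$y_deg[blk]
    xp <- kin$x_px[blk];  yp <- kin$y_px[blk]
    sp <- kin$vel_deg_s[blk]; ac <- kin$acc_deg_s2[blk]
    n <- length(blk)
    sac_sample <- (!is.na(sp) & sp > params$saccade_velocity_deg_s) |
      (!is.na(ac) & abs(ac) > params$saccade_accel_deg_s2)

    # maximal saccadic runs, validated on peak kinematics and amplitude
    r <- rle(sac_sample)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sac_mask <- rep(FALSE, n)
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      i0 <- starts[k]; i1 <- ends[k]
      # extend one sample each side for amplitude: the run excludes the
      # last below-threshold samples at launch/landing
      a0 <- max(1L, i0 - 1L); a1 <- min(n, i1 + 1L)
      amp <- sqrt((xd[a1] - xd[a0])^2 + (yd[a1] - yd[a0])^2)
      pv <- max(sp[i0:i1], na.rm = TRUE)
      pa <- suppressWarnings(max(abs(ac[i0:i1]), na.rm = TRUE))
      if (is.infinite(pa)) pa <- NA_real_
      if (pv > params$saccade_velocity_deg_s &&
          !is.na(pa) && pa > params$saccade_accel_deg_s2 &&
          amp > params$saccade_amplitude_deg) {
        sac_mask[i0:i1] <- TRUE
        events[[length(events) + 1L]] <- tibble::tibble(
          type = "saccade", onset_ms = t[i0], offset_ms = t[i1],
          duration_ms = t[i1] - t[i0],
          x_px = NA_real_, y_px = NA_real_, x_deg = NA_real_, y_deg = NA_real_,
          dispersion_deg = NA_real_, amplitude_deg = amp,
          peak_vel_deg_s = pv, peak_acc_deg_s2 = pa)
      }
    }

    # fixation candidates: maximal non-saccadic stretches
    r2 <- rle(!sac_mask)
    ends2 <- cumsum(r2$lengths)
    starts2 <- ends2 - r2$lengths + 1L
    for (k in seq_along(r2$values)) {
      if (!r2$values[k]) next
      i0 <- starts2[k]; i1 <- ends2[k]
      seg <- i0:i1
      for (rg in idt_carve(xd[seg], yd[seg], params$dispersion_deg)) {
        j <- seg[rg[1]:rg[2]]
        dur <- t[j[length(j)]] - t[j[1]]
        if (dur < params$min_fix_duration_ms) next
        cx <- mean(xp[j]); cy <- mean(yp[j])
        cdeg <- px_to_deg(geometry, cx, cy)
        cxd <- mean(xd[j]); cyd <- mean(yd[j])
        disp <- max(sqrt((xd[j] - cxd)^2 + (yd[j] - cyd)^2))
        events[[length(events) + 1L]] <- tibble::tibble(
          type = "fixation", onset_ms = t[j[1]], offset_ms = t[j[length(j)]],
          duration_ms = dur, x_px = cx, y_px = cy,
          x_deg = cdeg$x_deg, y_deg = cdeg$y_deg,
          dispersion_deg = disp, amplitude_deg = NA_real_,
          peak_vel_deg_s = NA_real_, peak_acc_deg_s2 = NA_real_)
      }
    }
  }
  if (!length(events)) return(empty)
  out <- dplyr::arrange(dplyr::bind_rows(events), .data$onset_ms)
  class(out) <- c("gaze_events", class(out))
  out
}

empty_events <- function() {
  out <- tibble::tibble(
    type = character(), onset_ms = numeric(), offset_ms = numeric(),
    duration_ms = numeric(), x_px = numeric(), y_px = numeric(),
    x_deg = numeric(), y_deg = numeric(), dispersion_deg = numeric(),
    amplitude_deg = numeric(), peak_vel_deg_s = numeric(),
    peak_acc_deg_s2 = numeric())
  class(out) <- c("gaze_events", class(out))
  out
}

#' Read / write detected events CSV
#'
#' Header `type,onset_ms,offset_ms,x_px,y_px,duration_ms,dispersion_deg,`
#' `amplitude_deg,peak_vel,peak_acc`; fixation rows leave the saccade
#' columns empty and vice versa.
#'
#' @param events A `gaze_events` tibble from [detect_events()].
#' @param path File path.
#' @return `read_events_csv()` returns a `gaze_events` tibble;
#'   `write_events_csv()` returns `path` invisibly.
#' @export
write_events_csv <- function(events, path) {
  out <- tibble::tibble(
    type = events$type, onset_ms = events$onset_ms,
    offset_ms = events$offset_ms, x_px = events$x_px, y_px = events$y_px,
    duration_ms = events$duration_ms, dispersion_deg = events$dispersion_deg,
    amplitude_deg = events$amplitude_deg, peak_vel = events$peak_vel_deg_s,
    peak_acc = events$peak_acc_deg_s2)
  readr::write_csv(out, path, progress = FALSE, na = "")
  invisible(path)
}

#' @rdname write_events_csv
#' @param geometry Optional [screen_geometry()]; if supplied, centroid
#'   degree coordinates are recomputed on read.
#' @export
read_events_csv <- function(path, geometry = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           type = readr::col_character(),
                           .default = readr::col_double()))
  out <- tibble::tibble(
    type = raw$type, onset_ms = raw$onset_ms, offset_ms = raw$offset_ms,
    duration_ms = raw$duration_ms, x_px = raw$x_px, y_px = raw$y_px,
    x_deg = NA_real_, y_deg = NA_real_,
    dispersion_deg = raw$dispersion_deg, amplitude_deg = raw$amplitude_deg,
    peak_vel_deg_s = raw$peak_vel, peak_acc_deg_s2 = raw$peak_acc)
  if (!is.null(geometry)) {
    deg <- px_to_deg(geometry, out$x_px, out$y_px)
    out$x_deg <- deg$x_deg
    out$y_deg <- deg$y_deg
  }
  class(out) <- c("gaze_events", class(out))
  out
}
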