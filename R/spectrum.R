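#' Cycles-per-degree scale of an image on screen
#'
#' Spatial frequency on a display is naturally counted in cycles across the
#' image; perceptually it is cycles per degree (cpd) of visual angle. For
#' `k` cycles across the image along one axis, the cpd is
#' `k / subtense_deg` where the subtense comes from exact trigonometry at
#' the rectangle edges (see [rect_subtense_deg()]).
#'
#' @param geometry A [screen_geometry()].
#' @param image_rect Displayed stimulus rectangle `c(x, y, w, h)` in screen
#'   pixels.
#' @return Named vector `c(x = , y = )`: cpd per image-cycle along each
#'   axis (anisotropic display pixels give different scales).
#' @export
cpd_per_cycle <- function(geometry, image_rect) {
  sub <- rect_subtense_deg(geometry, image_rect)
  if (any(sub <= 0)) stop("image_rect subtends a non-positive angle", call. = FALSE)
  c(x = 1 / sub[["x"]], y = 1 / sub[["y"]])
}

fft_cycles <- function(n) {
  k <- 0:(n - 1)
  pmin(k, n - k)
}

#' Fraction of image energy above a spatial-frequency threshold
#'
#' Computes the 2-D discrete Fourier power spectrum of a grayscale image,
#' excludes the DC bin, and reports the fraction of the remaining power at
#' radial frequency at or above `threshold_cpd`. Radial frequency combines
#' the per-axis cpd scales (so anisotropic pixels are handled); an optional
#' Hann window can be applied, but the default is the plain transform.
#'
#' This is the acuity-rationale computation: if virtually all stimulus
#' energy sits above a viewer's grating-acuity cutoff, the viewer cannot
#' resolve the stimulus content.
#'
#' @param image Numeric matrix (grayscale; RGB arrays are collapsed to
#'   Rec. 709 luminance).
#' @param geometry A [screen_geometry()].
#' @param image_rect Displayed rectangle `c(x, y, w, h)` in screen pixels.
#' @param threshold_cpd Radial-frequency threshold, cycles per degree.
#' @param window `"none"` (default) or `"hann"`.
#' @return A one-row tibble: `threshold_cpd`, `energy_fraction_above`,
#'   `total_power` (sum of non-DC spectral power).
#' @export
high_freq_energy_fraction <- function(image, geometry, image_rect,
                                      threshold_cpd = 3,
                                      window = c("none", "hann")) {
  window <- match.arg(window)
  if (length(dim(image)) == 3L) {
    image <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
  }
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (min(image) == max(image)) {
    warning("constant image has no non-DC energy; fraction defined as 0",
            call. = FALSE)
    return(tibble::tibble(threshold_cpd = threshold_cpd,
                          energy_fraction_above = 0, total_power = 0))
  }
  if (window == "hann") {
    hr <- 0.5 * (1 - cos(2 * pi * (seq_len(nrow(image)) - 1) / (nrow(image) - 1)))
    hc <- 0.5 * (1 - cos(2 * pi * (seq_len(ncol(image)) - 1) / (ncol(image) - 1)))
    image <- image * outer(hr, hc)
  }
  scale <- cpd_per_cycle(geometry, image_rect)
  # rows = y axis of the image, columns = x axis
  fy <- fft_cycles(nrow(image)) * scale[["y"]]
  fx <- fft_cycles(ncol(image)) * scale[["x"]]
  radial <- sqrt(outer(fy^2, fx^2, `+`))
  pw <- Mod(stats::fft(image))^2
  pw[1, 1] <- 0                       # exclude DC
  total <- sum(pw)
  frac <- if (total > 0) sum(pw[radial >= threshold_cpd]) / total else 0
  tibble::tibble(threshold_cpd = threshold_cpd,
                 energy_fraction_above = frac, total_power = total)
}

#' Spectrum report for one stimulus image
#'
#' Convenience wrapper of [high_freq_energy_fraction()] carrying the image
#' identifier, suitable for mapping over a stimulus set.
#'
#' @param image_id Identifier for the report.
#' @inheritParams high_freq_energy_fraction
#' @return One-row tibble: `image_id`, `threshold_cpd`,
#'   `energy_fraction_above`, `total_power`.
#' @export
spectrum_report <- function(image_id, image, geometry, image_rect,
                            threshold_cpd = 3, window = "none") {
  out <- high_freq_energy_fraction(image, geometry, image_rect,
                                   threshold_cpd, window)
  dplyr::bind_cols(tibble::tibble(image_id = image_id), out)
}
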