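#' Feature saliency maps
#'
#' A saliency map is a grayscale intensity grid over a stimulus image in
#' which brighter pixels mark regions predicted to attract attention for
#' one specific visual feature (e.g. "human faces", "red", "depth").
#' Maps are produced by an external generator backend (any program that,
#' given a stimulus image and a prompt, writes a grayscale PNG); this
#' package consumes the files, smooths and normalizes them, and scores
#' fixations against them.
#'
#' Internally a map is a numeric matrix (rows = image rows, columns = image
#' columns, matching the stimulus pixel grid) with attributes
#' `feature_label`, `normalized` and `constant`.
#'
#' @param intensities Numeric matrix of intensities.
#' @param feature_label Free-text feature label.
#' @param normalized Logical: are intensities integers in 0..255 produced
#'   by [smooth_and_normalize()]?
#' @param constant Logical: was the source map constant (no feature
#'   signal)? Constant maps are refused by the scoring stage.
#' @return An object of class `saliency_map`.
#' @export
saliency_map <- function(intensities, feature_label = NA_character_,
                         normalized = FALSE, constant = FALSE) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("intensities must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("saliency map contains non-finite values", call. = FALSE)
  }
  structure(intensities, feature_label = feature_label,
            normalized = normalized, constant = constant,
            class = c("saliency_map", "matrix", "array"))
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> '%s': %d x %d px, %s%s, range [%g, %g]\n",
              attr(x, "feature_label"), ncol(x), nrow(x),
              if (attr(x, "normalized")) "normalized 0-255" else "raw",
              if (attr(x, "constant")) " (constant)" else "",
              min(x), max(x)))
  invisible(x)
}

map_width  <- function(map) ncol(map)
map_height <- function(map) nrow(map)

# 1-D convolution with half-sample symmetric (reflective) padding. This
# padding implements a Neumann boundary, so a normalized kernel conserves
# total mass exactly: every out-of-range read folds back onto an in-range
# pixel with the same weight.
conv1_reflect <- function(x, kernel) {
  h <- (length(kernel) - 1L) / 2L
  if (h == 0L) return(x)
  n <- length(x)
  # map any integer index onto 1..n by half-sample symmetric reflection
  # (periodic with period 2n, so arbitrarily wide kernels tile correctly)
  i <- (1L - h):(n + h)
  m <- 2L * n
  j <- ((i - 1L) %% m + m) %% m            # 0 .. 2n-1
  idx <- ifelse(j < n, j + 1L, m - j)
  xp <- x[idx]
  out <- stats::filter(xp, kernel, sides = 2)
  as.numeric(out)[(h + 1L):(h + n)]
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

#' Gaussian smoothing of a raw map (separable, reflective boundary)
#'
#' @param raw Numeric matrix.
#' @param sigma_px Gaussian SD in pixels; 0 skips smoothing.
#' @return Smoothed matrix of the same dimensions; total mass is conserved
#'   exactly (reflective boundary, normalized kernel).
#' @export
gaussian_smooth <- function(raw, sigma_px) {
  if (sigma_px < 0) stop("sigma_px must be >= 0", call. = FALSE)
  if (sigma_px == 0) return(raw)
  k <- gaussian_kernel(sigma_px)
  sm <- apply(raw, 2L, conv1_reflect, kernel = k)        # down columns
  sm <- t(apply(sm, 1L, conv1_reflect, kernel = k))      # across rows
  dim(sm) <- dim(raw)
  sm
}

#' Smooth and normalize a raw saliency map
#'
#' Gaussian smoothing (reflective boundary) followed by min-max rescaling
#' onto the 8-bit range: the minimum maps to 0, the maximum to 255, and
#' values are rounded half-away-from-zero to integers, so any non-constant
#' map attains both 0 and 255 exactly. A constant raw map carries no
#' feature signal; it is mapped to all zeros and flagged `constant` (the
#' scoring stage refuses such maps).
#'
#' @param raw Numeric matrix of raw (real-valued) saliency.
#' @param sigma_px Gaussian SD in pixels (0 = no smoothing). The default
#'   `NULL` uses 2% of map width, a scale-free choice.
#' @param feature_label Label carried into the result.
#' @return A normalized [saliency_map()].
#' @export
smooth_and_normalize <- function(raw, sigma_px = NULL,
                                 feature_label = NA_character_) {
  if (inherits(raw, "saliency_map")) {
    if (is.na(feature_label)) feature_label <- attr(raw, "feature_label")
    raw <- unclass_map(raw)
  }
  if (!is.matrix(raw) || !is.numeric(raw) || any(!is.finite(raw))) {
    stop("raw map must be a finite numeric matrix", call. = FALSE)
  }
  if (is.null(sigma_px)) sigma_px <- 0.02 * ncol(raw)
  sm <- gaussian_smooth(raw, sigma_px)
  rng <- range(sm)
  if (rng[1] == rng[2]) {
    return(saliency_map(array(0, dim(raw)), feature_label,
                        normalized = TRUE, constant = TRUE))
  }
  scaled <- (sm - rng[1]) / (rng[2] - rng[1]) * 255
  saliency_map(matrix(floor(scaled + 0.5), nrow(raw), ncol(raw)),
               feature_label, normalized = TRUE, constant = FALSE)
}

#' Differential saliency map
#'
#' For paired opposite prompts (e.g. foreground vs background) the final
#' map is the subtraction of the two raw maps, smoothed and min-max
#' normalized over its full signed range (negative differences are
#' retained, not clipped, so the rescale spans the most-b-like to the
#' most-a-like pixel). Subtraction happens on the raw pre-normalization
#' values; normalizing first and then subtracting is a documented
#' alternative the package does not use.
#'
#' @param map_a,map_b Raw numeric matrices of identical dimensions
#'   (target prompt and opposite prompt).
#' @param sigma_px Gaussian SD in pixels applied to the difference.
#' @param feature_label Label for the result.
#' @return A normalized [saliency_map()] of `a - b`.
#' @export
differential_map <- function(map_a, map_b, sigma_px = 0,
                             feature_label = NA_character_) {
  a <- if (inherits(map_a, "saliency_map")) unclass_map(map_a) else map_a
  b <- if (inherits(map_b, "saliency_map")) unclass_map(map_b) else map_b
  if (!all(dim(a) == dim(b))) {
    stop(sprintf("map dimensions differ: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  }
  smooth_and_normalize(a - b, sigma_px, feature_label)
}

unclass_map <- function(map) {
  m <- unclass(map)
  attributes(m) <- list(dim = dim(map))
  m
}

#' Read / write saliency maps as 8-bit grayscale PNG
#'
#' Normalized maps round-trip losslessly through 8-bit grayscale PNG. RGB
#' input is collapsed to luminance with the Rec. 709 weights
#' (0.2126 R + 0.7152 G + 0.0722 B); input with more than 8 bits of
#' precision is down-converted to 8-bit with a warning.
#'
#' @param path PNG file path.
#' @param feature_label Label attached on read.
#' @param expect_dim Optional `c(height, width)`; a mismatch with the
#'   declared stimulus dimensions is an error.
#' @return `load_map_png()` returns a [saliency_map()] with integer
#'   intensities in 0..255 (marked normalized when it attains 0 and 255).
#' @export
load_map_png <- function(path, feature_label = NA_character_,
                         expect_dim = NULL) {
  if (!file.exists(path)) stop("map PNG not found: ", path, call. = FALSE)
  img <- png::readPNG(path)
  # depth check on the stored channels, before any luminance collapse
  if (max(abs(img * 255 - round(img * 255))) > 1e-6) {
    warning("map PNG has more than 8-bit precision; down-converting to 8-bit",
            call. = FALSE)
  }
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    img <- if (ch >= 3L) {
      0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    } else {
      img[, , 1]
    }
  }
  ints <- round(img * 255)
  if (!is.null(expect_dim) && !all(dim(ints) == expect_dim)) {
    stop(sprintf("map dimensions %dx%d do not match declared stimulus %dx%d",
                 nrow(ints), ncol(ints), expect_dim[1], expect_dim[2]),
         call. = FALSE)
  }
  constant <- min(ints) == max(ints)
  saliency_map(ints, feature_label,
               normalized = !constant && min(ints) == 0 && max(ints) == 255,
               constant = constant)
}

#' @rdname load_map_png
#' @param map A [saliency_map()] with intensities in 0..255.
#' @export
write_map_png <- function(map, path) {
  m <- unclass_map(map)
  if (min(m) < 0 || max(m) > 255) {
    stop("write_map_png expects intensities in [0, 255]; normalize first",
         call. = FALSE)
  }
  png::writePNG(m / 255, path)
  invisible(path)
}

#' Read a saliency-map manifest
#'
#' CSV with header `image_id,feature_label,map_path` linking each
#' (stimulus image, feature) pair to its grayscale PNG.
#'
#' @param path Manifest CSV path.
#' @param load Load the referenced PNGs into a `map` list-column?
#' @param base_dir Directory relative paths are resolved against (defaults
#'   to the manifest's directory).
#' @return A tibble `image_id, feature_label, map_path` (+ `map`).
#' @export
read_map_manifest <- function(path, load = TRUE, base_dir = dirname(path)) {
  man <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("image_id", "feature_label", "map_path")
  missing <- setdiff(need, names(man))
  if (length(missing)) {
    stop("map manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  man <- tibble::as_tibble(man)[need]
  if (load) {
    man$map <- purrr::map2(man$map_path, man$feature_label, function(p, f) {
      full <- if (file.exists(p)) p else file.path(base_dir, p)
      load_map_png(full, feature_label = f)
    })
  }
  man
}

#' Canonical feature-label vocabulary
#'
#' The default set of per-feature saliency prompts used in the study
#' design: four colors, visual-field half/center maps, luminance, contrast,
#' orientation, background, depth, animals, human faces and bodies,
#' movement and complexity.
#'
#' @return Character vector of feature labels.
#' @export
feature_vocabulary <- function() {
  c("red", "yellow", "green", "blue",
    "field_central", "field_peripheral", "field_upper", "field_lower",
    "field_right", "field_left",
    "luminance", "contrast", "orientation", "background", "depth",
    "animals", "human_faces", "human_bodies", "movement", "complexity")
}
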