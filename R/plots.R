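#' Plot detected events as a scanpath
#'
#' Fixations as points sized by duration, saccades as connecting
#' segments, over the screen (y axis flipped to match the top-left pixel
#' origin).
#'
#' @param object A `gaze_events` tibble from [detect_events()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot gaze_events
#' @export
autoplot.gaze_events <- function(object, ...) {
  fx <- dplyr::filter(tibble::as_tibble(object), .data$type == "fixation")
  ggplot2::ggplot(fx, ggplot2::aes(x = .data$x_px, y = .data$y_px)) +
    ggplot2::geom_path(color = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(size = .data$duration_ms),
                        alpha = 0.7, color = "#2166ac") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", size = "duration (ms)",
                  title = "Fixation scanpath") +
    ggplot2::theme_minimal()
}

#' Plot a saliency map
#'
#' Raster rendering of the intensity grid in image orientation.
#'
#' @param object A [saliency_map()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot saliency_map
#' @export
autoplot.saliency_map <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  df$intensity <- as.vector(unclass_map(object))[
    (df$col - 1L) * nrow(object) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = attr(object, "feature_label"),
                  x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Group comparison plot of fixation saliency summaries
#'
#' Boxplots of participant overall mean fixation saliency values per
#' feature, split by group.
#'
#' @param summaries Summary tibble from [score_session()] /
#'   [score_cohort()].
#' @return A ggplot object.
#' @export
plot_group_summaries <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$feature_label,
                               y = .data$overall_mean,
                               fill = .data$group_label)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, alpha = 0.8) +
    ggplot2::labs(x = NULL, y = "mean fixation saliency value (0-255)",
                  fill = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Map-over-image overlay for manual inspection
#'
#' Renders a stimulus image with a semi-transparent saliency overlay, the
#' standard visual check that a generated map highlights the intended
#' regions.
#'
#' @param image Grayscale matrix or RGB array in `[0, 1]`.
#' @param map A [saliency_map()] of the same width/height.
#' @param alpha Overlay opacity.
#' @return A ggplot object.
#' @export
plot_map_overlay <- function(image, map, alpha = 0.5) {
  if (length(dim(image)) == 3L) {
    image <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
  }
  stopifnot(all(dim(image) == dim(map)))
  df <- tidyr::expand_grid(row = seq_len(nrow(image)),
                           col = seq_len(ncol(image)))
  lin <- (df$col - 1L) * nrow(image) + df$row
  df$lum <- as.vector(image)[lin]
  df$sal <- as.vector(unclass_map(map))[lin] / 255
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$lum)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_raster(ggplot2::aes(alpha = .data$sal), fill = "red") +
    ggplot2::scale_alpha(range = c(0, alpha), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = attr(map, "feature_label"), x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
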