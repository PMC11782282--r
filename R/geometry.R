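#' Screen and viewing geometry
#'
#' Describes the physical display and viewing distance used during an
#' eye-tracking session. This object is the pixel-to-degree contract for the
#' whole package: every angular quantity (fixation dispersion, saccade
#' velocity, cycles per degree) is derived from it by exact trigonometry.
#'
#' The coordinate convention is the common eye-tracker one: pixel origin at
#' the top-left corner, x rightward, y downward, 0-based indices with pixel
#' centers at integer coordinates. Degrees of visual angle are measured from
#' the screen center, rightward/downward positive.
#'
#' @param width_px,height_px Display resolution in pixels.
#' @param width_cm,height_cm Physical display size in cm.
#' @param distance_cm Eye-to-screen distance in cm (a typical pediatric
#'   free-viewing setup places the child 60 cm from the monitor).
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry(1920, 1080, 53.1, 29.9, 60)
#' px_to_deg(geom, 959.5 + 37.87, 539.5)  # ~1 degree right of center
#' @export
screen_geometry <- function(width_px, height_px, width_cm, height_cm,
                            distance_cm) {
  vals <- c(width_px = width_px, height_px = height_px, width_cm = width_cm,
            height_cm = height_cm, distance_cm = distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen_geometry fields must be finite and strictly positive",
         call. = FALSE)
  }
  aspect_px <- width_px / height_px
  aspect_cm <- width_cm / height_cm
  if (abs(aspect_px / aspect_cm - 1) > 0.05) {
    warning(sprintf(
      "pixel aspect ratio (%.3f) and physical aspect ratio (%.3f) disagree by more than 5%%: pixels are markedly non-square",
      aspect_px, aspect_cm), call. = FALSE)
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         width_cm = width_cm, height_cm = height_cm,
         distance_cm = distance_cm),
    class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px, %.1f x %.1f cm, viewed at %.1f cm\n",
              x$width_px, x$height_px, x$width_cm, x$height_cm, x$distance_cm))
  cat(sprintf("  center pixel scale: %.3f px/deg (x), %.3f px/deg (y)\n",
              px_per_deg(x)[["x"]], px_per_deg(x)[["y"]]))
  invisible(x)
}

is_screen_geometry <- function(x) inherits(x, "screen_geometry")

assert_geometry <- function(geometry) {
  if (!is_screen_geometry(geometry)) {
    stop("`geometry` must be a screen_geometry object", call. = FALSE)
  }
  invisible(geometry)
}

# screen-center pixel coordinate (0-based, pixel centers at integers)
geometry_center_px <- function(geometry) {
  c(x = (geometry$width_px - 1) / 2, y = (geometry$height_px - 1) / 2)
}

cm_per_px <- function(geometry) {
  c(x = geometry$width_cm / geometry$width_px,
    y = geometry$height_cm / geometry$height_px)
}

#' Approximate linear pixel-per-degree scale at the screen center
#'
#' Small-angle scale used to convert angular noise magnitudes to pixels; all
#' positional conversions use the exact arctangent form in [px_to_deg()].
#'
#' @param geometry A [screen_geometry()].
#' @return Named vector with components `x` and `y`, pixels per degree.
#' @export
px_per_deg <- function(geometry) {
  assert_geometry(geometry)
  cpp <- cm_per_px(geometry)
  c(x = (pi / 180) * geometry$distance_cm / cpp[["x"]],
    y = (pi / 180) * geometry$distance_cm / cpp[["y"]])
}

#' Convert screen pixel coordinates to degrees of visual angle
#'
#' Exact per-axis arctangent conversion relative to the screen center:
#' `angle = atan(offset_cm / distance_cm)` where `offset_cm` is the pixel
#' offset from center times the physical cm-per-pixel scale. The small-angle
#' linear approximation is deliberately not used; the exact form costs
#' nothing and removes tangent-plane error at larger eccentricities.
#'
#' Points off the physical screen are permitted (the arctangent is defined
#' everywhere); `deg_to_px()` is the exact inverse.
#'
#' @param geometry A [screen_geometry()].
#' @param x_px,y_px Pixel coordinates (vectorized).
#' @return A tibble with columns `x_deg`, `y_deg`.
#' @seealso [deg_to_px()]
#' @export
px_to_deg <- function(geometry, x_px, y_px) {
  assert_geometry(geometry)
  ctr <- geometry_center_px(geometry)
  cpp <- cm_per_px(geometry)
  tibble::tibble(
    x_deg = atan2((x_px - ctr[["x"]]) * cpp[["x"]], geometry$distance_cm) * 180 / pi,
    y_deg = atan2((y_px - ctr[["y"]]) * cpp[["y"]], geometry$distance_cm) * 180 / pi)
}

#' Convert degrees of visual angle to screen pixel coordinates
#'
#' Exact inverse of [px_to_deg()]: `offset_px = distance_cm * tan(angle) /
#' cm_per_px`, offset measured from the screen-center pixel.
#'
#' @inheritParams px_to_deg
#' @param x_deg,y_deg Angles in degrees (vectorized).
#' @return A tibble with columns `x_px`, `y_px`.
#' @export
deg_to_px <- function(geometry, x_deg, y_deg) {
  assert_geometry(geometry)
  ctr <- geometry_center_px(geometry)
  cpp <- cm_per_px(geometry)
  tibble::tibble(
    x_px = ctr[["x"]] + geometry$distance_cm * tan(x_deg * pi / 180) / cpp[["x"]],
    y_px = ctr[["y"]] + geometry$distance_cm * tan(y_deg * pi / 180) / cpp[["y"]])
}

# Euclidean angular distance (deg) between two screen-pixel points, via the
# per-axis exact conversion. Used for dispersion and saccade amplitude.
angular_distance_deg <- function(geometry, x1, y1, x2, y2) {
  a <- px_to_deg(geometry, x1, y1)
  b <- px_to_deg(geometry, x2, y2)
  sqrt((a$x_deg - b$x_deg)^2 + (a$y_deg - b$y_deg)^2)
}

#' Angular subtense of a screen rectangle
#'
#' Horizontal and vertical visual angle spanned by a rectangle on the
#' display, from exact trigonometry at the rectangle's physical edges (a
#' rect covering pixels `x .. x+w-1` physically spans `x-0.5 .. x+w-0.5`
#' under the pixel-centers-at-integers convention).
#'
#' @param geometry A [screen_geometry()].
#' @param rect Numeric vector or list with elements `x`, `y`, `w`, `h`
#'   (screen pixels).
#' @return Named numeric vector `c(x = , y = )`, degrees.
#' @export
rect_subtense_deg <- function(geometry, rect) {
  assert_geometry(geometry)
  rect <- as_rect(rect)
  if (rect$w <= 0 || rect$h <= 0) stop("rect has zero or negative size", call. = FALSE)
  left  <- px_to_deg(geometry, rect$x - 0.5, rect$y - 0.5)
  right <- px_to_deg(geometry, rect$x + rect$w - 0.5, rect$y + rect$h - 0.5)
  c(x = right$x_deg - left$x_deg, y = right$y_deg - left$y_deg)
}

as_rect <- function(rect) {
  if (is.list(rect) || is.data.frame(rect)) {
    r <- list(x = rect$x %||% rect$rect_x, y = rect$y %||% rect$rect_y,
              w = rect$w %||% rect$rect_w, h = rect$h %||% rect$rect_h)
  } else {
    stopifnot(length(rect) == 4)
    nm <- names(rect)
    if (!is.null(nm) && all(c("x", "y", "w", "h") %in% nm)) {
      r <- list(x = rect[["x"]], y = rect[["y"]], w = rect[["w"]], h = rect[["h"]])
    } else {
      r <- list(x = rect[[1]], y = rect[[2]], w = rect[[3]], h = rect[[4]])
    }
  }
  if (any(vapply(r, is.null, logical(1))) || any(!is.finite(unlist(r)))) {
    stop("rect must supply finite x, y, w, h", call. = FALSE)
  }
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a
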