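#' Build a pixel-to-meter calibration from a marked object
#'
#' An object of known physical size marked in a frame fixes the scalar
#' meters-per-pixel scale: a line of known length, a rectangle of known
#' side lengths (e.g. the arena), or a circle of known diameter. Rectangle
#' and circle calibrations also move the world origin (designated corner
#' resp. circle center); a line keeps the pixel origin.
#'
#' @param kind `"line"`, `"rectangle"` or `"circle"`.
#' @param marks pixel coordinates: line = 2 points; rectangle = 4 corners
#'   in order; circle = center plus one rim point, or >= 3 rim points.
#' @param true_size physical size in meters: line length; rectangle
#'   `c(width, height)` of the sides `1-2` and `2-3`; circle diameter.
#' @param origin_corner for rectangles, which corner (1--4) becomes the
#'   world origin (default 1).
#' @param flip_y if `TRUE`, world +y points up (image y runs down).
#' @return An object of class `calibration`: `kind`, `scale` (m/px),
#'   `origin_px`, `flip_y` and, for rectangles, `side_disagreement`
#'   (relative difference between the two independent scale estimates).
#' @export
build_calibration <- function(kind = c("line", "rectangle", "circle"),
                              marks, true_size, origin_corner = 1L,
                              flip_y = FALSE) {
  kind <- match.arg(kind)
  marks <- matrix(as.numeric(marks), ncol = 2)
  if (any(true_size <= 0))
    stop("configuration error: true_size must be positive", call. = FALSE)
  disagreement <- NA_real_
  if (kind == "line") {
    if (nrow(marks) != 2L) stop("line needs 2 marks", call. = FALSE)
    d <- sqrt(sum((marks[2, ] - marks[1, ])^2))
    if (d < 1e-9) stop("configuration error: coincident marks", call. = FALSE)
    scale <- true_size[1] / d
    origin <- c(0, 0)
  } else if (kind == "rectangle") {
    if (nrow(marks) != 4L) stop("rectangle needs 4 corner marks", call. = FALSE)
    if (length(true_size) != 2L)
      stop("rectangle needs true_size = c(width, height)", call. = FALSE)
    side <- function(i, j) sqrt(sum((marks[j, ] - marks[i, ])^2))
    s_w <- mean(c(side(1, 2), side(3, 4)))
    s_h <- mean(c(side(2, 3), side(4, 1)))
    if (s_w < 1e-9 || s_h < 1e-9)
      stop("configuration error: coincident marks", call. = FALSE)
    est <- c(true_size[1] / s_w, true_size[2] / s_h)
    disagreement <- abs(diff(est)) / mean(est)
    if (disagreement > 0.10)
      warning(sprintf(paste("rectangle side ratio inconsistent with the",
                            "given true sizes (%.1f%% scale disagreement)"),
                      100 * disagreement))
    scale <- mean(est)
    origin <- marks[origin_corner, ]
  } else {
    if (nrow(marks) == 2L) {
      center <- marks[1, ]
      r <- sqrt(sum((marks[2, ] - marks[1, ])^2))
    } else if (nrow(marks) >= 3L) {
      # algebraic least-squares circle fit through the rim points
      A <- cbind(2 * marks[, 1], 2 * marks[, 2], 1)
      bb <- marks[, 1]^2 + marks[, 2]^2
      sol <- qr.solve(A, bb)
      center <- sol[1:2]
      r <- sqrt(sol[3] + sum(center^2))
    } else stop("circle needs center+rim or >= 3 rim points", call. = FALSE)
    if (r < 1e-9) stop("configuration error: coincident marks", call. = FALSE)
    scale <- true_size[1] / (2 * r)
    origin <- center
  }
  structure(list(kind = kind, scale = scale, origin_px = as.numeric(origin),
                 flip_y = flip_y, side_disagreement = disagreement),
            class = "calibration")
}

#' Transform pixel coordinates to world (meter) coordinates
#'
#' `world = (px - origin_px) * scale`, with the y axis optionally flipped.
#' The transform is an isotropic similarity: distances scale by exactly
#' `scale` and angles are preserved.
#'
#' @param points_px n x 2 matrix (or length-2 vector) of pixel coordinates.
#' @param cal a [calibration].
#' @return n x 2 matrix of world coordinates in meters.
#' @export
to_world <- function(points_px, cal) {
  stopifnot(inherits(cal, "calibration"))
  p <- matrix(as.numeric(points_px), ncol = 2)
  out <- sweep(p, 2, cal$origin_px) * cal$scale
  if (cal$flip_y) out[, 2] <- -out[, 2]
  out
}

#' Inverse of [to_world()]
#' @param points_m n x 2 matrix of world coordinates (m).
#' @param cal a [calibration].
#' @return n x 2 matrix of pixel coordinates.
#' @export
from_world <- function(points_m, cal) {
  stopifnot(inherits(cal, "calibration"))
  p <- matrix(as.numeric(points_m), ncol = 2)
  if (cal$flip_y) p[, 2] <- -p[, 2]
  sweep(p / cal$scale, 2, cal$origin_px, `+`)
}

#' Write / read a calibration as YAML
#' @param cal a [calibration].
#' @param path YAML file path.
#' @return `path` (write) or a [calibration] (read).
#' @export
write_calibration <- function(cal, path) {
  yaml::write_yaml(list(kind = cal$kind, scale_m_per_px = cal$scale,
                        origin_px = as.numeric(cal$origin_px),
                        flip_y = cal$flip_y), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  structure(list(kind = y$kind, scale = y$scale_m_per_px,
                 origin_px = as.numeric(y$origin_px), flip_y = isTRUE(y$flip_y),
                 side_disagreement = NA_real_),
            class = "calibration")
}
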