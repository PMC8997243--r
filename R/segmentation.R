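#' Difference image
#'
#' Per-pixel absolute difference between a frame and the background
#' estimate. Static structures cancel to ~0 while the moving animal
#' remains; using the absolute difference makes one code path serve both
#' dark-on-bright and bright-on-dark footage.
#'
#' @param frame H x W matrix in \[0,1\].
#' @param background `background_image` or H x W matrix.
#' @return H x W matrix in \[0,1\].
#' @export
difference_image <- function(frame, background) {
  if (inherits(background, "background_image")) background <- background$image
  if (!identical(dim(frame), dim(background)))
    stop("format error: frame and background dimensions differ", call. = FALSE)
  abs(frame - background)
}

#' Normalize an image to its maximum
#'
#' Divides by the image maximum so the brightest region (the animal, given
#' adequate contrast) sits at exactly 1.0 and the binarization threshold
#' becomes contrast-independent. An all-zero image is returned unchanged.
#'
#' @param img numeric matrix.
#' @return matrix with maximum 1 (or all zeros).
#' @export
normalize_image <- function(img) {
  m <- max(img)
  if (m <= 0) return(img)
  img / m
}

#' Binarize a normalized image
#'
#' Pixels strictly greater than `threshold` become foreground; ties go to
#' background so the rule is deterministic.
#'
#' @param img numeric matrix (normally normalized to max 1).
#' @param threshold scalar in (0, 1); 0.25 is the canonical default for
#'   high-contrast difference images.
#' @return logical H x W matrix with attribute `threshold`.
#' @export
binarize <- function(img, threshold = 0.25) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("configuration error: threshold must lie strictly in (0, 1)",
         call. = FALSE)
  mask <- img > threshold
  attr(mask, "threshold") <- threshold
  mask
}

#' Region of interest
#'
#' @param shape `"rectangle"` or `"polygon"`.
#' @param vertices n x 2 matrix of (x, y) pixel coordinates (0-based;
#'   x = column, y = row). A rectangle is given by two opposite corners.
#' @return An object of class `roi`.
#' @export
roi <- function(shape = c("rectangle", "polygon"), vertices) {
  shape <- match.arg(shape)
  vertices <- matrix(as.numeric(vertices), ncol = 2)
  if (shape == "polygon" && nrow(vertices) < 3L)
    stop("configuration error: polygon ROI needs >= 3 vertices", call. = FALSE)
  if (shape == "rectangle" && nrow(vertices) != 2L)
    stop("configuration error: rectangle ROI is two opposite corners",
         call. = FALSE)
  structure(list(shape = shape, vertices = vertices), class = "roi")
}

#' Mask out pixels outside a region of interest
#'
#' @param mask logical H x W matrix.
#' @param region an [roi], or `NULL` for a no-op.
#' @return logical matrix with everything outside the ROI set to `FALSE`.
#' @export
apply_roi <- function(mask, region) {
  if (is.null(region)) return(mask)
  stopifnot(inherits(region, "roi"))
  h <- nrow(mask); w <- ncol(mask)
  v <- region$vertices
  if (region$shape == "rectangle") {
    x0 <- min(v[, 1]); x1 <- max(v[, 1])
    y0 <- min(v[, 2]); y1 <- max(v[, 2])
    if (x1 < 0 || y1 < 0 || x0 > w - 1 || y0 > h - 1)
      stop("configuration error: ROI lies fully outside the image",
           call. = FALSE)
    keep <- matrix(FALSE, h, w)
    xs <- max(0, ceiling(x0)):min(w - 1, floor(x1))
    ys <- max(0, ceiling(y0)):min(h - 1, floor(y1))
    keep[ys + 1, xs + 1] <- TRUE
  } else {
    xs <- rep(0:(w - 1), each = h)
    ys <- rep(0:(h - 1), times = w)
    inside <- pracma::inpolygon(xs, ys, v[, 1], v[, 2], boundary = TRUE)
    keep <- matrix(inside, h, w)
    if (!any(keep))
      stop("configuration error: ROI lies fully outside the image",
           call. = FALSE)
  }
  out <- mask & keep
  attr(out, "threshold") <- attr(mask, "threshold")
  out
}

#' Morphological erosion of a binary mask
#'
#' Erodes with a disk structuring element; used to cut the thin contact
#' bridge between two touching animals so that each yields its own
#' connected component. Radius 0 is the identity.
#'
#' @param mask logical H x W matrix.
#' @param radius disk radius in pixels (integer >= 0).
#' @return logical matrix, a subset of the input.
#' @export
erode_mask <- function(mask, radius = 1L) {
  if (length(radius) != 1L || is.na(radius) || radius < 0)
    stop("configuration error: erosion radius must be >= 0", call. = FALSE)
  radius <- as.integer(radius)
  if (radius == 0L) return(mask)
  img <- EBImage::Image(t(mask * 1))
  er <- EBImage::erode(img, EBImage::makeBrush(2L * radius + 1L, "disc"))
  out <- t(EBImage::imageData(er)) > 0.5
  attr(out, "threshold") <- attr(mask, "threshold")
  out
}

#' Extract outer boundaries of foreground components
#'
#' Labels connected foreground components and traces one closed outer
#' contour per component, dropping components whose enclosed polygon area
#' falls below `min_area` (noise specks). Holes are ignored. Contours are
#' returned in order of decreasing area.
#'
#' @param mask logical H x W matrix.
#' @param min_area minimum enclosed area in px^2.
#' @return list of `contour` objects: `points` (n x 2, 0-based x,y, closed
#'   chain without repeating the first point), `length_px` (perimeter) and
#'   `area_px` (shoelace area).
#' @export
extract_boundaries <- function(mask, min_area = 0) {
  if (!any(mask)) return(list())
  lab <- EBImage::bwlabel(EBImage::Image(t(mask * 1)))
  oc <- EBImage::ocontour(lab)
  res <- list()
  for (pts in oc) {
    if (is.null(pts) || nrow(pts) < 3L) next
    per <- sum(sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), ])^2)))
    area <- abs(pracma::polyarea(pts[, 1], pts[, 2]))
    if (area < min_area) next
    res[[length(res) + 1L]] <- structure(
      list(points = unname(pts), length_px = per, area_px = area),
      class = "contour")
  }
  if (length(res) > 1L)
    res <- res[order(vapply(res, function(ct) ct$area_px, numeric(1)),
                     decreasing = TRUE)]
  res
}
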