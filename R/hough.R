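#' Ellipse detection parameters
#'
#' @param min_major,max_major admissible full major-axis length in px
#'   (0 < min < max). These bounds are implicit to the Hough detection:
#'   point pairs outside the range never vote.
#' @param n_animals expected number of animals in the scene (user prior).
#' @param quality_threshold accumulator quality in (0,1) above which a
#'   candidate counts as an accepted detection.
#' @param max_subthreshold_kept how many below-threshold candidates to keep
#'   per frame for the correction stages.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(min_major, max_major, n_animals = 1L,
                             quality_threshold = 0.3,
                             max_subthreshold_kept = 10L) {
  if (!(min_major > 0 && min_major < max_major))
    stop("configuration error: need 0 < min_major < max_major", call. = FALSE)
  if (n_animals < 1L)
    stop("configuration error: n_animals must be >= 1", call. = FALSE)
  structure(list(min_major = min_major, max_major = max_major,
                 n_animals = as.integer(n_animals),
                 quality_threshold = quality_threshold,
                 max_subthreshold_kept = as.integer(max_subthreshold_kept)),
            class = "detection_params")
}

#' Expected full major-axis length of a single animal
#'
#' The mean of the admissible bounds; used wherever a "single animal size"
#' is needed (chain splitting, post-hoc distance scale).
#' @param params a [detection_params].
#' @return length in px.
#' @export
expected_major <- function(params) (params$min_major + params$max_major) / 2

# Ramanujan's perimeter approximation; the ideal vote count of a complete
# ellipse whose boundary is sampled at ~1 px spacing.
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Polygon approximation of an ellipse outline
#'
#' @param x,y center; `a`,`b` semi-axes; `theta` orientation in degrees.
#' @param n number of polygon vertices.
#' @return n x 2 matrix of (x, y) coordinates.
#' @export
ellipse_polygon <- function(x, y, a, b, theta, n = 60L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  th <- theta * pi / 180
  ex <- a * cos(t); ey <- b * sin(t)
  cbind(x + ex * cos(th) - ey * sin(th),
        y + ex * sin(th) + ey * cos(th))
}

# intersection-over-minimum area of two ellipses (polygon clipping)
ellipse_iom <- function(d1, d2, n = 60L) {
  p1 <- ellipse_polygon(d1$x, d1$y, d1$a, d1$b, d1$theta, n)
  p2 <- ellipse_polygon(d2$x, d2$y, d2$a, d2$b, d2$theta, n)
  inter <- polyclip::polyclip(list(x = p1[, 1], y = p1[, 2]),
                              list(x = p2[, 1], y = p2[, 2]), op = "intersection")
  if (length(inter) == 0L) return(0)
  ai <- sum(vapply(inter, function(p) abs(pracma::polyarea(p$x, p$y)),
                   numeric(1)))
  ai / min(pi * d1$a * d1$b, pi * d2$a * d2$b)
}

#' Detect ellipses in a set of edge points
#'
#' Pair-sampling Hough transform: each admissible pair of edge points is
#' treated as the endpoints of the major axis; the other points vote in a
#' 1-D accumulator for the implied semi-minor length. The peak gives the
#' candidate (center = pair midpoint, a = half pair distance, orientation =
#' pair angle, b = peak bin). Quality is the peak vote count normalized by
#' the Ramanujan perimeter of the candidate — the vote count a complete,
#' densely sampled ellipse would achieve — clipped to \[0,1\]. Partially
#' occluded ellipses still vote coherently and are found with reduced
#' quality. Pairs are enumerated exhaustively up to 400 edge points; larger
#' sets are subsampled uniformly at random (seeded, reproducible).
#'
#' Near-duplicate candidates (accumulator echo) are removed by greedy
#' non-maximum suppression on >60% intersection-over-minimum area overlap,
#' keeping the higher quality. Genuine multi-animal overlap handling
#' belongs to the correction stage, which sees all surviving candidates.
#'
#' @param edge_points n x 2 matrix of (x, y) edge coordinates.
#' @param params a [detection_params].
#' @param rng_seed integer seed for the point subsampling.
#' @param min_votes minimum raw accumulator votes for a candidate; if no
#'   candidate reaches it the single best one is still returned so the
#'   correction stage always has something to score.
#' @return data.frame with columns `x, y, a, b, theta, quality,
#'   subthreshold`, sorted by decreasing quality. `theta` is in degrees,
#'   normalized to \[0, 180).
#' @export
detect_ellipses <- function(edge_points, params, rng_seed = 1L,
                            min_votes = 5L) {
  empty <- data.frame(x = numeric(0), y = numeric(0), a = numeric(0),
                      b = numeric(0), theta = numeric(0),
                      quality = numeric(0), subthreshold = logical(0))
  if (is.null(edge_points) || NROW(edge_points) < 3L) return(empty)
  pts <- matrix(as.numeric(edge_points), ncol = 2)
  if (nrow(pts) > 400L) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(as.integer(rng_seed))
    pts <- pts[sort(sample.int(nrow(pts), 400L)), , drop = FALSE]
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  cand <- hough_pairs(pts[, 1], pts[, 2], params$min_major,
                      params$max_major, as.integer(min_votes))
  if (nrow(cand) == 0L)
    cand <- hough_pairs(pts[, 1], pts[, 2], params$min_major,
                        params$max_major, 1L)
  if (nrow(cand) == 0L) return(empty)

  q <- pmin(1, cand[, "votes"] / ellipse_perimeter(cand[, "a"], cand[, "b"]))
  theta <- (cand[, "theta"] * 180 / pi) %% 180
  df <- data.frame(x = cand[, "cx"], y = cand[, "cy"], a = cand[, "a"],
                   b = cand[, "b"], theta = theta, quality = q)

  # coarse dedupe: many pairs describe the same ellipse
  key <- paste(round(df$x), round(df$y), round(df$a), round(df$b),
               round(df$theta / 5))
  df <- df[order(-df$quality), ]
  df <- df[!duplicated(key[order(-q)]), , drop = FALSE]
  df <- head(df, 100L)

  # accumulator-echo dedupe: jittered endpoint pairs of the same physical
  # ellipse yield candidates with near-identical center and axes but
  # slightly tilted (often mirrored) orientations; for thin ellipses these
  # share little area, so they must be removed by parameter proximity.
  # Genuinely crossing animals differ strongly in orientation and survive.
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (j in which(keep)) {
      dc <- sqrt((df$x[i] - df$x[j])^2 + (df$y[i] - df$y[j])^2)
      dth <- abs(((df$theta[i] - df$theta[j]) + 90) %% 180 - 90)
      if (dc <= 3 && abs(df$a[i] - df$a[j]) <= 0.15 * df$a[j] &&
          dth <= 15) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  df <- df[keep, , drop = FALSE]

  # greedy non-maximum suppression on mutual area overlap
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (ellipse_iom(df[i, ], df[j, ]) > 0.6) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  df <- df[keep, , drop = FALSE]
  df$subthreshold <- df$quality < params$quality_threshold
  rownames(df) <- NULL
  df
}

#' Split a frame into per-boundary sub-images
#'
#' The Hough transform is brute force, so the frame is cut into padded
#' crops that each contain a single boundary's edge pixels; detection then
#' runs per crop and offsets map results back to frame coordinates.
#'
#' @param mask logical H x W frame mask (only used for clipping bounds).
#' @param contours list of contours from [extract_boundaries()].
#' @param pad padding in px around each contour's bounding box.
#' @return list with one element per contour: `points` (edge coordinates in
#'   crop frame), `offset` (x0, y0 of the crop origin in frame
#'   coordinates), `size` (crop H, W) and `edge` (logical crop with the
#'   contour pixels set).
#' @export
split_subimages <- function(mask, contours, pad = 5L) {
  h <- nrow(mask); w <- ncol(mask)
  lapply(contours, function(ct) {
    p <- ct$points
    x0 <- max(0, floor(min(p[, 1])) - pad)
    y0 <- max(0, floor(min(p[, 2])) - pad)
    x1 <- min(w - 1, ceiling(max(p[, 1])) + pad)
    y1 <- min(h - 1, ceiling(max(p[, 2])) + pad)
    loc <- cbind(p[, 1] - x0, p[, 2] - y0)
    edge <- matrix(FALSE, y1 - y0 + 1, x1 - x0 + 1)
    edge[cbind(round(loc[, 2]) + 1, round(loc[, 1]) + 1)] <- TRUE
    list(points = loc, offset = c(x0, y0), size = c(y1 - y0 + 1, x1 - x0 + 1),
         edge = edge)
  })
}
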