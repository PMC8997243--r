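# arc-length resampling of an (optionally closed) polyline to n points
resample_polyline <- function(pts, n, closed = FALSE) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (closed) pts <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- if (closed) seq(0, total, length.out = n + 1L)[seq_len(n)] else
    seq(0, total, length.out = n)
  cbind(approx(s, pts[, 1], xout = target, ties = "ordered")$y,
        approx(s, pts[, 2], xout = target, ties = "ordered")$y)
}

# minimum distance from points to a closed polygon boundary
dist_to_polygon <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  a <- poly
  b <- poly[c(2:nrow(poly), 1), ]
  ab <- b - a
  len2 <- rowSums(ab^2)
  apply(pts, 1, function(p) {
    t <- ((p[1] - a[, 1]) * ab[, 1] + (p[2] - a[, 2]) * ab[, 2]) /
      pmax(len2, 1e-12)
    t <- pmin(1, pmax(0, t))
    qx <- a[, 1] + t * ab[, 1]; qy <- a[, 2] + t * ab[, 2]
    sqrt(min((p[1] - qx)^2 + (p[2] - qy)^2))
  })
}

# maximum caliper diameter of a point set (via its convex hull)
max_diameter <- function(pts) {
  hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  d2 <- outer(seq_len(nrow(hull)), seq_len(nrow(hull)), function(i, j)
    (hull[i, 1] - hull[j, 1])^2 + (hull[i, 2] - hull[j, 2])^2)
  sqrt(max(d2))
}

#' Sample evenly spaced seed points from a contour
#'
#' Picks `n` points at equal arc-length spacing along the closed contour,
#' starting at its first point. These are the Voronoi seeds of the
#' pseudo-skeleton construction; 100 seeds is the canonical count.
#'
#' @param contour a `contour` from [extract_boundaries()], or an m x 2
#'   matrix of ordered boundary points.
#' @param n number of seeds (default 100). If the contour has fewer than
#'   `n` boundary points, `n` is reduced to that count.
#' @return n x 2 matrix of (x, y) seed coordinates.
#' @export
sample_contour <- function(contour, n = 100L) {
  pts <- if (inherits(contour, "contour")) contour$points else contour
  if (NROW(pts) < 3L)
    stop("contract error: degenerate contour (< 3 points)", call. = FALSE)
  n <- min(as.integer(n), nrow(pts))
  resample_polyline(pts, n, closed = TRUE)
}

#' Build the interior Voronoi graph of a contour
#'
#' Computes the Voronoi tessellation of the seed points and keeps only the
#' finite tessellation edges whose *both* endpoints lie strictly inside the
#' contour. Because the seeds sit on the boundary, the surviving vertices
#' concentrate along the body mid-line (a discrete medial-axis
#' approximation). Vertices are deduplicated within 1e-6 px.
#'
#' @param seeds n x 2 matrix from [sample_contour()].
#' @param contour the source contour (object or m x 2 matrix).
#' @return An object of class `skeleton_graph`: `vertices` (v x 2 matrix),
#'   `edges` (data.frame `i, j, w` with Euclidean weights) and `empty`
#'   flag signalling that no interior vertex survived.
#' @export
build_skeleton_graph <- function(seeds, contour) {
  poly <- if (inherits(contour, "contour")) contour$points else contour
  if (NROW(seeds) < 4L)
    stop("contract error: need >= 4 seeds", call. = FALSE)
  seeds <- unique(round(matrix(as.numeric(seeds), ncol = 2), 9))
  # break exact collinearity/cocircularity, which stalls the tessellation;
  # the deterministic perturbation (1e-4 px) is far below pixel noise
  k <- seq_len(nrow(seeds))
  seeds[, 1] <- seeds[, 1] + 1e-4 * cos(k * 2.399963)
  seeds[, 2] <- seeds[, 2] + 1e-4 * sin(k * 1.618034)
  rw <- c(min(poly[, 1]) - 2, max(poly[, 1]) + 2,
          min(poly[, 2]) - 2, max(poly[, 2]) + 2)
  utils::capture.output(
    dd <- suppressWarnings(suppressMessages(
      deldir::deldir(seeds[, 1], seeds[, 2], rw = rw, suppressMsge = TRUE))))
  sg <- dd$dirsgs
  inside1 <- pracma::inpolygon(sg$x1, sg$y1, poly[, 1], poly[, 2],
                               boundary = FALSE)
  inside2 <- pracma::inpolygon(sg$x2, sg$y2, poly[, 1], poly[, 2],
                               boundary = FALSE)
  keep <- inside1 & inside2 & !sg$bp1 & !sg$bp2
  sg <- sg[keep, , drop = FALSE]
  if (nrow(sg) == 0L)
    return(structure(list(vertices = matrix(numeric(0), 0, 2),
                          edges = data.frame(i = integer(0), j = integer(0),
                                             w = numeric(0)),
                          empty = TRUE),
                     class = "skeleton_graph"))
  vkey <- function(x, y) paste(round(x / 1e-6), round(y / 1e-6))
  keys <- c(vkey(sg$x1, sg$y1), vkey(sg$x2, sg$y2))
  xs <- c(sg$x1, sg$x2); ys <- c(sg$y1, sg$y2)
  uk <- !duplicated(keys)
  verts <- cbind(xs[uk], ys[uk])
  idx <- match(keys, keys[uk])
  m <- nrow(sg)
  i <- idx[seq_len(m)]; j <- idx[m + seq_len(m)]
  w <- sqrt((sg$x1 - sg$x2)^2 + (sg$y1 - sg$y2)^2)
  ok <- w > 0 & i != j
  edges <- unique(data.frame(i = pmin(i, j)[ok], j = pmax(i, j)[ok],
                             w = w[ok]))
  structure(list(vertices = verts, edges = edges, empty = FALSE),
            class = "skeleton_graph")
}

# choose the contour point extending the midline beyond an end vertex:
# nearest contour point inside a 45-degree cone around the outward tangent
tip_extension <- function(end, neighbor, poly) {
  u <- end - neighbor
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) return(NULL)
  u <- u / nu
  rel <- sweep(poly, 2, end)
  along <- rel[, 1] * u[1] + rel[, 2] * u[2]
  lateral <- abs(rel[, 1] * (-u[2]) + rel[, 2] * u[1])
  cone <- along > 0 & along >= lateral
  if (!any(cone)) cone <- along > 0
  if (!any(cone)) return(NULL)
  d <- sqrt(rowSums(rel^2))
  d[!cone] <- Inf
  poly[which.min(d), ]
}

#' Extract the mid-line path of a skeleton graph
#'
#' Endpoints are the vertex pair maximizing the geodesic (graph) distance
#' penalized by the vertices' distance to the contour: the medial axis
#' approaches the boundary at the body ends, so the winning pair combines
#' maximal mutual path length with closeness to the boundary. (Selecting
#' purely by boundary distance is brittle: binarization noise creates
#' isolated near-boundary vertices mid-body.) The pseudo-skeleton is the
#' minimum-total-length (Dijkstra) path between the endpoints. If the graph
#' is disconnected the pair is confined to the largest component and the
#' result is flagged. Optionally each end is extended to the nearest
#' contour point ahead of the path so the reported length spans tip to tip.
#'
#' @param graph a `skeleton_graph`.
#' @param contour the source contour (object or m x 2 matrix).
#' @param extend_tips extend the path ends to the contour (default `TRUE`).
#' @param smooth apply a 3-point moving average to the interior vertices
#'   (default `FALSE`).
#' @return An object of class `pseudo_skeleton`: `points` (ordered chain),
#'   `length_px` (sum of segment lengths), `path_weight` (graph path
#'   weight, excluding tip extensions) and `fallback` flag.
#' @export
midline_path <- function(graph, contour, extend_tips = TRUE, smooth = FALSE) {
  poly <- if (inherits(contour, "contour")) contour$points else contour
  if (graph$empty || nrow(graph$vertices) < 2L)
    stop("empty skeleton graph", call. = FALSE)
  v <- graph$vertices
  bdist <- dist_to_polygon(v, poly)
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$edges$i, to = graph$edges$j),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(v))))
  igraph::E(g)$weight <- graph$edges$w
  dmat <- igraph::distances(g, weights = igraph::E(g)$weight)
  fallback <- !igraph::is_connected(g)
  score <- dmat - outer(bdist, bdist, `+`)
  score[!is.finite(dmat)] <- -Inf
  diag(score) <- -Inf
  ij <- which(score == max(score), arr.ind = TRUE)[1, ]
  sp <- suppressWarnings(igraph::shortest_paths(
    g, from = ij[1], to = ij[2], weights = igraph::E(g)$weight,
    output = "vpath"))
  path_idx <- as.integer(igraph::as_ids(sp$vpath[[1]]))
  pts <- v[path_idx, , drop = FALSE]
  path_weight <- sum(sqrt(rowSums(diff(pts)^2)))
  if (smooth && nrow(pts) >= 3L) {
    sm <- pts
    inner <- 2:(nrow(pts) - 1)
    sm[inner, ] <- (pts[inner - 1, ] + pts[inner, ] + pts[inner + 1, ]) / 3
    pts <- sm
  }
  if (extend_tips && nrow(pts) >= 2L) {
    head_ext <- tip_extension(pts[1, ], pts[2, ], poly)
    tail_ext <- tip_extension(pts[nrow(pts), ], pts[nrow(pts) - 1, ], poly)
    if (!is.null(head_ext)) pts <- rbind(head_ext, pts)
    if (!is.null(tail_ext)) pts <- rbind(pts, tail_ext)
  }
  structure(list(points = unname(pts),
                 length_px = sum(sqrt(rowSums(diff(pts)^2))),
                 path_weight = path_weight, fallback = fallback),
            class = "pseudo_skeleton")
}

#' Pseudo-skeleton of a contour
#'
#' Convenience wrapper chaining [sample_contour()] (default 100 seeds),
#' [build_skeleton_graph()] and [midline_path()].
#'
#' @param contour a `contour` or m x 2 boundary matrix.
#' @param n_seeds number of contour seeds (default 100).
#' @param ... passed to [midline_path()].
#' @return A `pseudo_skeleton`, or `NULL` if no interior vertex survives.
#' @export
skeletonize <- function(contour, n_seeds = 100L, ...) {
  seeds <- sample_contour(contour, n_seeds)
  g <- build_skeleton_graph(seeds, contour)
  if (g$empty || nrow(g$vertices) < 2L) return(NULL)
  midline_path(g, contour, ...)
}

#' Mean bending angle of a pseudo-skeleton
#'
#' Resamples the skeleton to `k_segments` equal segments and returns the
#' mean angle between consecutive segment directions at the interior
#' joints, expressed so that a perfectly straight skeleton gives 180
#' degrees and bent shapes give less.
#'
#' @param skel a `pseudo_skeleton` or an m x 2 point chain.
#' @param k_segments number of segments for resampling (default 10).
#' @return angle in degrees in (0, 180\].
#' @export
bending_angle <- function(skel, k_segments = 10L) {
  pts <- if (inherits(skel, "pseudo_skeleton")) skel$points else skel
  if (NROW(pts) < 3L)
    stop("contract error: need >= 3 skeleton points", call. = FALSE)
  k <- as.integer(k_segments)
  r <- resample_polyline(pts, k + 1L)
  d <- diff(r)
  ang <- atan2(d[, 2], d[, 1])
  turn <- diff(ang)
  turn <- (turn + pi) %% (2 * pi) - pi
  mean(180 - abs(turn) * 180 / pi)
}

#' Eccentricity of a detected ellipse
#'
#' @param det one-row detection data.frame (or list) with semi-axes `a`,
#'   `b`, or a numeric vector `c(a, b)`.
#' @return `sqrt(1 - (b/a)^2)` in \[0, 1).
#' @export
eccentricity <- function(det) {
  if (is.numeric(det)) { a <- det[1]; b <- det[2] }
  else { a <- det$a; b <- det$b }
  stopifnot(a >= b, b > 0)
  sqrt(1 - (b / a)^2)
}
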