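circle_contour <- function(cx = 30, cy = 30, r = 20, n = 120L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

test_that("contour seeds are evenly spaced in arc length", {
  sq <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  s4 <- sample_contour(sq, 4)
  expect_equal(nrow(s4), 4L)
  gaps <- sqrt(rowSums((s4 - s4[c(2:4, 1), ])^2))
  expect_equal(gaps, rep(100, 4))
  ct <- circle_contour(n = 500)
  s100 <- sample_contour(ct, 100)
  expect_equal(nrow(s100), 100L)
  arc <- sqrt(rowSums((s100 - s100[c(2:100, 1), ])^2))
  expect_lt(diff(range(arc)), 1)
  expect_error(sample_contour(rbind(c(0, 0), c(1, 1)), 10), "degenerate")
})

test_that("interior Voronoi vertices trace the medial axis", {
  # circle: vertices cluster at the center
  ct <- circle_contour()
  g <- build_skeleton_graph(sample_contour(ct, 60), ct)
  expect_false(g$empty)
  d <- sqrt((g$vertices[, 1] - 30)^2 + (g$vertices[, 2] - 30)^2)
  expect_lt(max(d), 2)
  # rectangle: middle 80% of vertices sit on the central axis
  rc <- rect_contour()                     # 200 x 20 at (10, 10)
  gr <- build_skeleton_graph(sample_contour(rc, 100), rc)
  v <- gr$vertices
  mid <- v[v[, 1] > 10 + 20 & v[, 1] < 10 + 180, , drop = FALSE]
  expect_gt(nrow(mid), 10)
  expect_lt(max(abs(mid[, 2] - 20)), 1)
  # postcondition: every vertex strictly inside the contour
  expect_true(all(pracma::inpolygon(v[, 1], v[, 2], rc[, 1], rc[, 2])))
})

test_that("midline of a rectangle follows the true axis", {
  rc <- rect_contour()
  s <- skeletonize(rc)
  expect_gt(s$length_px, 180)          # at least the straight axis segment
  expect_lt(s$length_px, 225)          # axis + corner diagonals + tips
  mid <- s$points[s$points[, 1] > 10 + 20 & s$points[, 1] < 10 + 180, ]
  expect_lt(max(abs(mid[, 2] - 20)), 1.5)
  # containment and scale equivariance
  expect_true(all(pracma::inpolygon(s$points[, 1], s$points[, 2],
                                    rc[, 1], rc[, 2], boundary = TRUE)))
  s2 <- skeletonize(rc * 2)
  expect_lt(abs(s2$length_px / s$length_px - 2), 0.02 * 2)
})

test_that("midline path weight equals exhaustive enumeration on small graphs", {
  # hand-built 4-vertex graph: 3-edge chain of weight 3 vs a 2.5 shortcut
  g <- structure(list(
    vertices = rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0)),
    edges = data.frame(i = c(1, 2, 3, 1), j = c(2, 3, 4, 4),
                       w = c(1, 1, 1, 2.5)),
    empty = FALSE), class = "skeleton_graph")
  ig <- igraph::graph_from_data_frame(
    data.frame(from = g$edges$i, to = g$edges$j), directed = FALSE,
    vertices = data.frame(name = 1:4))
  w_dij <- igraph::distances(ig, v = 1, to = 4, weights = g$edges$w)[1, 1]
  expect_equal(w_dij, 2.5)
  expect_equal(w_dij, brute_shortest_path(g$edges, 1, 4, 4))
  # random small graphs: Dijkstra == exhaustive path enumeration
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(4:6, 1)
    full <- t(combn(n, 2))
    pick <- full[runif(nrow(full)) < 0.7, , drop = FALSE]
    if (nrow(pick) < n - 1) next
    edges <- data.frame(i = pick[, 1], j = pick[, 2],
                        w = round(runif(nrow(pick), 0.1, 5), 3))
    ig <- igraph::graph_from_data_frame(
      data.frame(from = edges$i, to = edges$j), directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    w <- suppressWarnings(
      igraph::distances(ig, v = 1, to = n, weights = edges$w)[1, 1])
    brute <- brute_shortest_path(edges, 1, n, n)
    expect_equal(w, brute, tolerance = 1e-9)
  }
})

test_that("reversing skeleton polarity preserves the path length", {
  rc <- rect_contour()
  s <- skeletonize(rc)
  rev_pts <- s$points[nrow(s$points):1, ]
  len_rev <- sum(sqrt(rowSums(diff(rev_pts)^2)))
  expect_equal(len_rev, s$length_px, tolerance = 1e-9)
})

test_that("skeleton length recovers programmed body-length modulation", {
  sc <- make_crawler(n_frames = 150, seed = 13)
  cfg <- pipeline_config(min_major = 70, max_major = 150, n_animals = 1)
  res <- run_pipeline(sc$seq, cfg, stages = "pose")
  lens <- vapply(res$skeletons, function(s)
    if (is.null(s)) NA_real_ else s$length_px, numeric(1))
  truth <- sc$truth$body_length[res$track$frame]
  ok <- !is.na(lens)
  expect_gt(mean(ok), 0.98)
  expect_gt(cor(lens[ok], truth[ok]), 0.98)
  expect_lt(sqrt(mean((lens[ok] - truth[ok])^2)) / mean(truth), 0.03)
  # containment on every frame
  for (t in c(20, 75, 130)) {
    s <- res$skeletons[[t]]
    ct <- midliner:::match_contour(res$track[t, ], res$contours[[t]])
    expect_true(all(pracma::inpolygon(s$points[, 1], s$points[, 2],
                                      ct$points[, 1], ct$points[, 2],
                                      boundary = TRUE)))
  }
})

test_that("bending angle is 180 for a line, 90 for an elbow, 162 for an arc", {
  line <- cbind(seq(0, 100, by = 5), 0)
  expect_equal(bending_angle(line, 10), 180)
  elbow <- rbind(c(0, 0), c(10, 0), c(10, 10))
  expect_equal(bending_angle(elbow, 2), 90)
  th <- seq(0, pi, length.out = 201)
  arc <- cbind(50 * cos(th), 50 * sin(th))
  expect_equal(bending_angle(arc, 10), 162, tolerance = 0.5)
  expect_error(bending_angle(rbind(c(0, 0), c(1, 1)), 10), ">= 3")
})

test_that("eccentricity follows the closed form and is monotone", {
  expect_equal(eccentricity(c(5, 5)), 0)
  expect_equal(eccentricity(c(2, 1)), sqrt(3) / 2, tolerance = 1e-4)
  ratios <- seq(0.95, 0.1, by = -0.05)
  eccs <- vapply(ratios, function(r) eccentricity(c(1, r)), numeric(1))
  expect_true(all(diff(eccs) > 0))
})
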