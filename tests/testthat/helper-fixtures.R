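# shared fixtures and independent oracles (kept deliberately simple and
# separate from the implementation paths they check)

# closed rectangle contour traced at ~1 px spacing
rect_contour <- function(w = 200, h = 20, x0 = 10, y0 = 10) {
  xs <- seq(x0, x0 + w); ys <- seq(y0, y0 + h)
  rbind(cbind(xs, y0),
        cbind(x0 + w, ys[-1]),
        cbind(rev(xs)[-1], y0 + h),
        cbind(x0, rev(ys)[-c(1, length(ys))]))
}

# logical disk mask
disk_mask <- function(H, W, cx, cy, r) {
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# all permutations of 1..n (for the assignment brute force)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# brute-force minimum-cost assignment over all permutations (square cost)
brute_assignment_cost <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  for (p in all_perms(n)) {
    tot <- sum(cost[cbind(seq_len(n), unlist(p))])
    if (tot < best) best <- tot
  }
  best
}

# exhaustive shortest-path weight by simple-path enumeration
brute_shortest_path <- function(edges, from, to, n_vertices) {
  adj <- vector("list", n_vertices)
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]; w <- edges$w[r]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  best <- Inf
  walk <- function(v, visited, acc) {
    if (acc >= best) return()
    if (v == to) { best <<- acc; return() }
    nb <- adj[[v]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) {
      u <- nb[r, 1]
      if (!visited[u]) { visited[u] <- TRUE; walk(u, visited, acc + nb[r, 2])
        visited[u] <- FALSE }
    }
  }
  visited <- rep(FALSE, n_vertices); visited[from] <- TRUE
  walk(from, visited, 0)
  best
}

# brute-force optimal makespan by enumerating all core assignments
brute_makespan <- function(durations, n_cores) {
  n <- length(durations)
  best <- Inf
  rec <- function(i, loads) {
    if (max(loads) >= best) return()
    if (i > n) { best <<- max(loads); return() }
    for (c in seq_len(n_cores)) {
      loads[c] <- loads[c] + durations[i]
      rec(i + 1L, loads)
      loads[c] <- loads[c] - durations[i]
    }
  }
  rec(1L, numeric(n_cores))
  best
}

# independent trapezoid integration (plain loop, no library calls)
trapz_loop <- function(x, y) {
  s <- 0
  for (k in seq_len(length(x) - 1L))
    s <- s + (x[k + 1] - x[k]) * (y[k] + y[k + 1]) / 2
  s
}

# independent curvature-index oracle: resample with approx, rotate the
# chord onto the y axis, integrate the lateral coordinate with trapz_loop
oracle_curvature <- function(pts, n_points = 101L) {
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  tgt <- seq(0, s[length(s)], length.out = n_points)
  rx <- approx(s, pts[, 1], tgt)$y
  ry <- approx(s, pts[, 2], tgt)$y
  rx <- rx - rx[1]; ry <- ry - ry[1]
  phi <- atan2(ry[n_points], rx[n_points])
  rot <- pi / 2 - phi
  lat <- rx * cos(rot) - ry * sin(rot)
  idx <- seq_len(n_points) - 1
  I_abs <- trapz_loop(idx, abs(lat))
  I <- trapz_loop(idx, lat)
  (I_abs - I) * (-sign(lat[ceiling(n_points / 2)]))
}

# one-row candidate data.frame
mk_cand <- function(x, y, a, b, theta, q, subthreshold = q < 0.3) {
  data.frame(x = x, y = y, a = a, b = b, theta = theta, quality = q,
             subthreshold = subthreshold)
}

# constructed per-frame detections exercising a given problem code.
# params: min_major 60, max_major 120 (expected single-animal major 90).
problem_params <- function() detection_params(60, 120, n_animals = 2L)

problem_case <- function(code) {
  p <- problem_params()
  cand <- switch(as.character(code),
    "1" = rbind(mk_cand(50, 50, 40, 10, 0, 0.85),     # n=1 handled below
                mk_cand(51, 50, 40, 10, 5, 0.60)),
    "2" = rbind(mk_cand(40, 40, 40, 10, 0, 0.9),
                mk_cand(140, 40, 40, 10, 0, 0.8),
                mk_cand(240, 40, 40, 10, 0, 0.7)),
    "3" = rbind(mk_cand(40, 40, 40, 10, 0, 0.9),
                mk_cand(41, 40, 40, 10, 3, 0.5),      # overlays the first
                mk_cand(140, 40, 40, 10, 0, 0.8),
                mk_cand(260, 40, 40, 10, 0, 0.4)),    # disjoint surplus
    "4" = rbind(mk_cand(40, 40, 40, 10, 0, 0.9),
                mk_cand(150, 40, 40, 10, 0, 0.25),
                mk_cand(260, 40, 40, 10, 0, 0.15)),
    "5" = rbind(mk_cand(100, 40, 72, 10, 0, 0.7)),    # 2a=144 >= 1.5*90
    "6" = rbind(mk_cand(100, 40, 72, 10, 0, 0.7),     # splits into 2 < 3
                mk_cand(300, 40, 40, 10, 0, 0.2)),
    "7" = rbind(mk_cand(100, 40, 72, 10, 0, 0.7),
                mk_cand(300, 40, 40, 10, 0, 0.9)))
  n_animals <- switch(as.character(code), "1" = 1L, "6" = 3L, 2L)
  cfg <- correction_config(n_animals = n_animals)
  list(dets = frame_detections(1L, cand, p), cfg = cfg, params = p)
}
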