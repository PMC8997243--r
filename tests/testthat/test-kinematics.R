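test_that("contraction amplitude follows its defining ratio", {
  expect_equal(contraction_amplitude(rep(100, 10)), 0)
  expect_equal(contraction_amplitude(c(100, 92, 80, 95)), 20)
  expect_error(contraction_amplitude(c(100, -3)), "positive")
  expect_error(contraction_amplitude(100), ">= 2")
  # bounds and monotonicity in programmed depth
  set.seed(4)
  amps <- c(5, 15, 30, 45)
  got <- vapply(amps, function(A) {
    tt <- seq(0, 4, by = 0.05)
    contraction_amplitude(100 * (1 - A / 100 * (0.5 - 0.5 * cos(2 * pi * tt))))
  }, numeric(1))
  expect_true(all(got >= 0 & got < 100))
  expect_true(all(diff(got) > 0))
  expect_equal(got, amps, tolerance = 1e-6)
})

test_that("curvature index is zero for straight, signed for C-bends", {
  straight <- cbind(seq(0, 100, 2), 5)
  expect_equal(curvature_index(straight), 0, tolerance = 1e-9)
  # parabolic C-bends: compare against the independent integration oracle.
  # The formula is asymmetric by construction: the bend on one lateral side
  # yields c = 2 * I_abs > 0, its mirror collapses to 0, so equality with
  # the oracle is asserted rather than sign-antisymmetry.
  x <- seq(-50, 50, length.out = 101)
  bend <- cbind(x, -0.01 * (50^2 - x^2))
  bend2 <- cbind(x, 0.01 * (50^2 - x^2))
  c1 <- curvature_index(bend); c2 <- curvature_index(bend2)
  expect_equal(c1, oracle_curvature(bend), tolerance = 1e-9)
  expect_equal(c2, oracle_curvature(bend2), tolerance = 1e-9)
  expect_equal(sort(abs(c(c1, c2))), c(0, max(abs(c(c1, c2)))))
  expect_gt(max(abs(c(c1, c2))), 100)       # the non-degenerate side
  # 20 random smooth skeletons match the oracle to 1e-9
  set.seed(77)
  for (rep in 1:20) {
    xr <- seq(0, 80, length.out = 51)
    yr <- 10 * sin(xr / runif(1, 8, 25) + runif(1, 0, 6)) +
      runif(1, -0.1, 0.1) * xr
    pts <- cbind(xr, yr)
    expect_equal(curvature_index(pts), oracle_curvature(pts),
                 tolerance = 1e-9)
  }
  # symmetric variant: C-bend is all turn, mirror-independent magnitude
  v <- curvature_index(bend2, variant = "symmetric")
  vm <- curvature_index(bend, variant = "symmetric")
  expect_gt(abs(v["turn"]), 0)
  expect_equal(abs(v["turn"]), abs(vm["turn"]), tolerance = 1e-9)
  expect_lt(v["s_shape"], abs(v["turn"]))
  # s-shape: signed integral cancels, s_shape component dominates
  s_pts <- cbind(x, 8 * sin(x / 8))
  vs <- curvature_index(s_pts, variant = "symmetric")
  expect_gt(vs["s_shape"], abs(vs["turn"]))
})

test_that("turn detection finds threshold-crossing intervals", {
  expect_equal(nrow(detect_turns(rep(1, 50), 5)), 0L)
  x <- rep(0, 100); x[40:55] <- 10
  iv <- detect_turns(x, 5)
  expect_equal(iv$start, 40L); expect_equal(iv$end, 55L)
  # merging across short gaps, min duration filter
  x2 <- rep(0, 100); x2[10:20] <- 10; x2[22:30] <- 10; x2[60] <- 10
  iv2 <- detect_turns(x2, 5, min_duration = 3, gap_frames = 3)
  expect_equal(nrow(iv2), 1L)
  expect_equal(c(iv2$start, iv2$end), c(10L, 30L))
})

test_that("ego-centric decomposition matches construction", {
  fps <- 10
  # straight motion along the heading at 0.10 m/s
  pos <- cbind(seq(0, 1, by = 0.01), 0)
  h <- rep(0, nrow(pos))
  ev <- ego_velocities(pos, h, fps)
  expect_equal(ev$thrust, rep(0.10, nrow(pos)), tolerance = 1e-9)
  expect_equal(ev$slip, rep(0, nrow(pos)), tolerance = 1e-9)
  expect_equal(ev$yaw_velocity, rep(0, nrow(pos)))
  # heading fixed perpendicular to motion: all slip
  ev2 <- ego_velocities(pos, rep(90, nrow(pos)), fps)
  expect_equal(ev2$thrust, rep(0, nrow(pos)), tolerance = 1e-9)
  expect_equal(abs(ev2$slip), rep(0.10, nrow(pos)), tolerance = 1e-9)
  # in-place rotation at 90 deg/frame, 200 fps
  h3 <- seq(0, by = 90, length.out = 20)
  ev3 <- ego_velocities(matrix(0, 20, 2), h3, 200)
  expect_equal(ev3$yaw_velocity[2:19], rep(18000, 18))
  expect_equal(ev3$thrust, rep(0, 20))
  # energy decomposition holds on arbitrary tracks
  set.seed(5)
  pos4 <- apply(matrix(rnorm(60, 0, 0.01), 30, 2), 2, cumsum)
  h4 <- cumsum(rnorm(30, 0, 10))
  ev4 <- ego_velocities(pos4, h4, 25)
  expect_lt(max(abs(ev4$thrust^2 + ev4$slip^2 - ev4$speed^2)), 1e-9)
})

test_that("axial orientations resolve to stable directed headings", {
  # motion along +x with axial theta near 0/180: heading stays near 0
  pos <- cbind(seq(0, 50, by = 1), 0)
  theta <- rep(c(1, 179.5, 0.5, 178), length.out = nrow(pos))
  theta_cont <- midliner:::unwrap_deg(theta * 2) / 2
  h <- resolve_heading(theta_cont, pos)
  expect_true(all(abs(((h + 180) %% 360 - 180)) < 10))
  # motion along -x flips by 180
  h2 <- resolve_heading(theta_cont, pos[nrow(pos):1, ])
  norm2 <- (h2 + 180) %% 360 - 180
  expect_true(all(abs(abs(norm2) - 180) < 10))
})

test_that("event peaks respect threshold and separation", {
  expect_equal(find_event_peaks(rep(0, 50), 1), integer(0))
  tt <- 1:300
  s <- 250 * exp(-((tt - 60) / 6)^2) + 150 * exp(-((tt - 150) / 6)^2) +
    300 * exp(-((tt - 240) / 6)^2)
  ev <- find_event_peaks(s, 200, 10)
  expect_equal(ev, c(60L, 240L))
  # conflict inside min_separation keeps the larger peak
  s2 <- rep(0, 60); s2[25] <- 5; s2[28] <- 7
  expect_equal(find_event_peaks(s2, 1, 10), 28L)
  expect_equal(find_event_peaks(s2, 1, 2), c(25L, 28L))
  # negative-going peaks count via |series|
  expect_equal(find_event_peaks(-s, 200, 10), c(60L, 240L))
})

test_that("triggered averages converge like a mean of noisy windows", {
  pulse <- c(rep(0, 10), 1:5, 5:1, rep(0, 10))
  series <- rep(pulse, 6)
  events <- which(series == 5 & seq_along(series) %% 30 == 15)
  ta <- triggered_average(series, events, window = 8, band = "sd")
  expect_equal(ta$n_events, length(events))
  expect_equal(max(ta$mean), 5)
  expect_equal(ta$upper, ta$mean)          # identical windows: zero spread
  expect_null(triggered_average(series, integer(0), 8))
  # single event: mean equals that window
  ta1 <- triggered_average(series, events[1], 8)
  expect_equal(ta1$mean, series[events[1] + (-8:8)])
  # pointwise error of the mean shrinks ~ sigma/sqrt(N)
  set.seed(8)
  sigma <- 0.5
  err_for <- function(N) {
    long <- rep(pulse, N + 2)
    ev <- seq(30 + 14, by = 30, length.out = N)  # the first "5" per pulse
    noisy <- long + rnorm(length(long), 0, sigma)
    ta <- triggered_average(noisy, ev, 8, band = "sd")
    sqrt(mean((ta$mean - long[ev[1] + (-8:8)])^2))
  }
  e10 <- mean(replicate(20, err_for(10)))
  e100 <- mean(replicate(20, err_for(100)))
  expect_lt(e100, e10 / 2)                 # expect ~ sqrt(10) ~ 3.2x
})

test_that("event frequency is count over duration", {
  expect_equal(event_frequency(c(10, 200, 900), 30), 0.1)
  expect_equal(event_frequency(integer(0), 30), 0)
  # invariant to rescaling the series above the threshold margin
  s <- rep(0, 300); s[c(50, 150, 250)] <- 3
  n1 <- length(find_event_peaks(s, 1, 10))
  n2 <- length(find_event_peaks(s * 7, 1, 10))
  expect_equal(n1, n2)
})

test_that("permutation test on medians matches exhaustive enumeration", {
  expect_equal(permutation_median_test(c(1, 2, 3), c(1, 2, 3)), 1)
  # full enumeration over all C(6,3) = 20 splits, counted independently
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  pool <- c(a, b)
  t_obs <- abs(median(a) - median(b))
  hits <- 0L; total <- 0L
  for (bits in 0:63) {
    idx <- which(bitwAnd(bits, 2^(0:5)) > 0)
    if (length(idx) != 3) next
    total <- total + 1L
    t_perm <- abs(median(pool[idx]) - median(pool[-idx]))
    if (t_perm >= t_obs - 1e-12) hits <- hits + 1L
  }
  expect_equal(total, 20L)
  p_exh <- permutation_median_test(a, b, exhaustive = TRUE)
  expect_equal(p_exh, hits / total)
  # sampled variant agrees within binomial Monte-Carlo error, reproducibly
  set.seed(10)
  a2 <- rnorm(8); b2 <- rnorm(9) + 0.8
  p_full <- permutation_median_test(a2, b2, exhaustive = TRUE)
  p_s <- permutation_median_test(a2, b2, n_permutations = 2000,
                                 exhaustive = FALSE, seed = 42)
  se <- sqrt(p_full * (1 - p_full) / 2000)
  expect_lt(abs(p_s - p_full), 3 * se + 1 / 2001)
  expect_equal(p_s, permutation_median_test(a2, b2, n_permutations = 2000,
                                            exhaustive = FALSE, seed = 42))
})

test_that("median thrust is stable under frame-rate halving", {
  sc <- make_crawler(n_frames = 200, seed = 31)
  tt <- seq_len(200)
  pos <- sc$truth$center * 5e-4
  h <- sc$truth$heading_deg
  ev_full <- ego_velocities(pos, h, 34)
  ev_half <- ego_velocities(pos[seq(1, 200, 2), ], h[seq(1, 200, 2)], 17)
  expect_lt(abs(median(ev_half$thrust) / median(ev_full$thrust) - 1), 0.05)
})
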