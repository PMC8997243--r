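test_that("generators are deterministic given the seed", {
  a <- make_crawler(n_frames = 15, seed = 6)
  b <- make_crawler(n_frames = 15, seed = 6)
  expect_identical(a$seq$frames, b$seq$frames)
  expect_identical(a$truth$midline, b$truth$midline)
  d <- make_crawler(n_frames = 15, seed = 7)
  expect_false(identical(a$seq$frames, d$seq$frames))
})

test_that("programmed contraction fixes the min/max length ratio", {
  sc <- make_crawler(n_frames = 68, amplitude = 15, period_s = 1, seed = 2)
  r <- min(sc$truth$body_length) / max(sc$truth$body_length)
  expect_equal(r, 0.85, tolerance = 1e-6)
  sc0 <- make_crawler(n_frames = 68, amplitude = 0, seed = 2)
  expect_equal(diff(range(sc0$truth$body_length)), 0)
  expect_error(make_crawler(amplitude = 70), "amplitude")
})

test_that("rendered silhouette centroid matches the true center", {
  sc <- make_crawler(n_frames = 40, speed = 2.0, seed = 14,
                     turns = list(list(start_s = 0.3, end_s = 0.9,
                                       angle_deg = 60)))
  bg <- sc$truth$empty_background
  for (t in c(5, 20, 35)) {
    d <- abs(sc$seq$frames[[t]] - bg)
    m <- d > 0.3
    xs <- which(m, arr.ind = TRUE)
    centroid <- c(mean(xs[, 2]) - 1, mean(xs[, 1]) - 1)   # (x, y), 0-based
    expect_lt(sqrt(sum((centroid - sc$truth$center[t, ])^2)), 2)
  }
})

test_that("background regimes change pixels but not the truth", {
  u <- make_swimmer(n_frames = 12, seed = 9, regime = "uniform")
  g <- make_swimmer(n_frames = 12, seed = 9, regime = "gradient")
  expect_identical(u$truth$midline, g$truth$midline)
  expect_identical(u$truth$heading_deg, g$truth$heading_deg)
  expect_false(identical(u$seq$frames[[1]], g$seq$frames[[1]]))
  # gradient regime really ramps the illumination
  bgg <- g$truth$empty_background
  expect_gt(mean(bgg[, ncol(bgg)]) - mean(bgg[, 1]), 0.05)
})

test_that("swimmer glides to rest without events", {
  sw <- make_swimmer(n_frames = 150, seed = 4, initial_speed = 0.08)
  sp <- sw$truth$speed_px
  expect_true(all(diff(sp) <= 1e-9))
  expect_lt(sp[150], sp[1] * 0.1)
})

test_that("two animals render two components outside events", {
  ma <- make_multianimal(n = 2, n_frames = 20, seed = 3)
  bg <- ma$truth$empty_background
  for (t in c(5, 15)) {
    m <- abs(ma$seq$frames[[t]] - bg) > 0.3
    expect_equal(length(extract_boundaries(m, min_area = 50)), 2L)
  }
})

test_that("chaining windows merge the silhouettes into one component", {
  ma <- make_multianimal(n = 2, n_frames = 30, chain_windows = list(c(10, 20)),
                         chain_overlap_px = 12, seed = 7)
  bg <- ma$truth$empty_background
  m_in <- abs(ma$seq$frames[[15]] - bg) > 0.3
  expect_equal(length(extract_boundaries(m_in, min_area = 50)), 1L)
  m_out <- abs(ma$seq$frames[[3]] - bg) > 0.3
  expect_equal(length(extract_boundaries(m_out, min_area = 50)), 2L)
})

test_that("pipeline problem codes follow the chaining schedule", {
  ma <- make_multianimal(n = 2, n_frames = 80, chain_windows = list(c(35, 50)),
                         chain_overlap_px = 12, seed = 7)
  cfg <- pipeline_config(min_major = 40, max_major = 170, n_animals = 2,
                         min_area = 120)
  res <- run_pipeline(ma$seq, cfg, stages = "track")
  codes <- vapply(res$frames, function(d) d$problem_code, integer(1))
  expect_true(all(codes[35:50] %in% 5:7))
  outside <- codes[c(1:32, 53:80)]
  expect_gte(mean(outside == 0), 0.95)
  expect_equal(res$summary$frac_accepted, 1)
})

test_that("a constructed detection corpus covers every problem code", {
  seen <- vapply(1:7, function(code) {
    cs <- problem_case(code)
    classify_problem(cs$dets, cs$cfg, 90)
  }, integer(1))
  expect_setequal(seen, 1:7)
})

test_that("one programmed saccade is recovered at threshold 200 not 400", {
  sw <- make_swimmer(n_frames = 200, seed = 5,
                     saccades = list(list(time_s = 0.3, peak_deg_s = 300)),
                     thrusts = list(list(time_s = 0.5, peak_m_s = 0.25)))
  cfg <- pipeline_config(min_major = 55, max_major = 110, n_animals = 1,
                         min_area = 150, smooth_frames = 9)
  cal <- build_calibration("line", rbind(c(0, 0), c(100, 0)),
                           100 * sw$truth$scale_m_per_px)
  res <- run_pipeline(sw$seq, cfg, cal = cal)
  k <- res$kinematics[["1"]]
  core <- 10:190                      # skip one-sided-derivative edges
  yv <- replace(k$yaw_velocity, -core, 0)
  sac200 <- find_event_peaks(yv, 200, min_separation = 20)
  sac400 <- find_event_peaks(yv, 400, min_separation = 20)
  expect_length(sac200, 1L)
  expect_lt(abs(sac200 - 0.3 * 200), 8)
  expect_length(sac400, 0L)
  # the programmed thrust stroke appears as the strongest thrust peak
  th <- replace(k$thrust, -core, 0)
  ev <- find_event_peaks(th, 0.10, min_separation = 20)
  expect_gt(length(ev), 0L)
  strongest <- ev[which.max(abs(th[ev]))]
  expect_lt(abs(strongest - 0.5 * 200), 20)
})
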