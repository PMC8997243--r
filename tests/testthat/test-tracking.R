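test_that("each standard problem is classified by its defining situation", {
  for (code in 1:7) {
    cs <- problem_case(code)
    expect_equal(classify_problem(cs$dets, cs$cfg, 90), code,
                 label = sprintf("code %d", code))
  }
  # clean two-animal frame -> 0
  cs <- problem_case(2)
  clean <- frame_detections(1L, rbind(mk_cand(40, 40, 40, 10, 0, 0.9),
                                      mk_cand(140, 40, 40, 10, 0, 0.8)),
                            problem_params())
  expect_equal(classify_problem(clean, cs$cfg, 90), 0L)
})

test_that("ad-hoc rules restore the animal-count prior", {
  for (code in 1:7) {
    cs <- problem_case(code)
    out <- apply_adhoc(cs$dets, cs$cfg, 90)
    expect_equal(nrow(out$accepted), cs$cfg$n_animals,
                 label = sprintf("code %d count", code))
    expect_equal(out$problem_code, code)
    expect_false(out$unresolved)
  }
})

test_that("surplus rules keep the best-quality detections", {
  # overlapping pair, n=1: keep the better one, quality untouched
  cs <- problem_case(1)
  out <- apply_adhoc(cs$dets, cs$cfg, 90)
  expect_equal(out$accepted$quality, 0.85)
  expect_false(out$accepted$corrected)
  # disjoint surplus, n=2: keep 0.9 and 0.8
  cs <- problem_case(2)
  out <- apply_adhoc(cs$dets, cs$cfg, 90)
  expect_setequal(out$accepted$quality, c(0.9, 0.8))
})

test_that("deficit is filled from the sub-threshold list with quality -1", {
  cs <- problem_case(4)
  out <- apply_adhoc(cs$dets, cs$cfg, 90)
  expect_setequal(out$accepted$quality, c(0.9, -1))
  filled <- out$accepted[out$accepted$corrected, ]
  expect_equal(filled$orig_quality, 0.25)   # best sub-threshold first
  # no candidates at all -> unresolved, logged
  empty <- frame_detections(1L, mk_cand(40, 40, 40, 10, 0, 0.9),
                            problem_params())
  out2 <- apply_adhoc(empty, correction_config(2), 90)
  expect_true(out2$unresolved)
  expect_equal(nrow(out2$accepted), 1L)
})

test_that("chain splitting follows the geometric construction", {
  p <- detection_params(60, 100)            # expected major 80
  det <- mk_cand(200, 50, 80, 12, 0, 0.7)   # full major 160
  kids <- split_chain(det, p)
  expect_equal(nrow(kids), 2L)
  expect_equal(sort(kids$x), c(160, 240))   # +-40 along the axis
  expect_equal(kids$y, c(50, 50))           # horizontal chain: same y
  expect_equal(kids$a, rep(40, 2))          # mean admissible major / 2
  expect_equal(kids$b, rep(12, 2))
  expect_true(all(kids$quality == -1))
  # boundary ratio 1.5 -> k = 2
  det15 <- mk_cand(0, 0, 60, 10, 90, 0.5)   # 120 = 1.5 * 80
  expect_equal(nrow(split_chain(det15, p)), 2L)
  expect_error(split_chain(mk_cand(0, 0, 40, 10, 0, .5), p), "oversized")
  # oblique chain: children on the major axis
  detq <- mk_cand(0, 0, 80, 10, 45, 0.6)
  kq <- split_chain(detq, p)
  expect_equal(kq$x, kq$y, tolerance = 1e-9)   # 45-degree axis
})

test_that("post-hoc estimators score by position, surface and contour", {
  p <- problem_params()
  prev <- apply_adhoc(frame_detections(1L, mk_cand(100, 100, 45, 10, 0, .9),
                                       p), correction_config(1), 90)
  nxt <- apply_adhoc(frame_detections(3L, mk_cand(104, 100, 45, 10, 0, .9),
                                      p), correction_config(1), 90)
  # position only: nearer candidate wins
  cur <- frame_detections(2L, rbind(mk_cand(104, 100, 45, 10, 0, 0.2),
                                    mk_cand(112, 100, 45, 10, 0, 0.25)), p)
  out <- posthoc_rescue(prev, cur, nxt,
                        correction_config(1, weights = c(pos = 1)), 90)
  expect_equal(out$accepted$x, 104)
  expect_equal(out$accepted$quality, -1)
  # surface only: candidate with area closer to the reference wins
  cur2 <- frame_detections(2L, rbind(mk_cand(300, 300, 45, 10.5, 0, 0.2),
                                     mk_cand(102, 100, 45, 40, 0, 0.25)), p)
  out2 <- posthoc_rescue(prev, cur2, nxt,
                         correction_config(1, weights = c(surf = 1)), 90)
  expect_equal(out2$accepted$x, 300)
  # exact tie -> higher raw Hough quality wins
  cur3 <- frame_detections(2L, rbind(mk_cand(98, 100, 45, 10, 0, 0.15),
                                     mk_cand(106, 100, 45, 10, 0, 0.25)), p)
  out3 <- posthoc_rescue(prev, cur3, nxt,
                         correction_config(1, weights = c(pos = 1)), 90)
  expect_equal(out3$accepted$orig_quality, 0.25)
})

test_that("identity assignment is the Hungarian optimum", {
  # obvious optimum
  m <- assign_identities(rbind(c(0, 0), c(10, 0)), rbind(c(1, 0), c(9, 0)))
  expect_equal(m, c(1L, 2L))
  # equals the brute-force permutation minimum on random instances
  set.seed(123)
  for (rep in 1:100) {
    n <- sample(2:6, 1)
    prev <- matrix(runif(2 * n, 0, 100), n, 2)
    cur <- matrix(runif(2 * n, 0, 100), n, 2)
    idx <- assign_identities(prev, cur)
    cost <- outer(seq_len(n), seq_len(n), function(i, j)
      sqrt((prev[i, 1] - cur[j, 1])^2 + (prev[i, 2] - cur[j, 2])^2))
    got <- sum(cost[cbind(idx, seq_len(n))])
    expect_equal(got, brute_assignment_cost(cost), tolerance = 1e-9)
  }
  # surplus current detections get new identities
  m2 <- assign_identities(rbind(c(0, 0), c(10, 0)),
                          rbind(c(0, 1), c(10, 1), c(50, 50)))
  expect_equal(sum(is.na(m2)), 1L)
  expect_true(is.na(m2[3]))
})

test_that("identities stay constant on well-separated trajectories", {
  # the clip must be long enough for each body to clear its own footprint,
  # or the temporal background projection retains a smear
  ma <- make_multianimal(n = 2, n_frames = 100, seed = 8)
  cfg <- pipeline_config(min_major = 60, max_major = 120, n_animals = 2,
                         min_area = 120)
  res <- run_pipeline(ma$seq, cfg, stages = "track")
  tr <- res$track
  expect_equal(nrow(tr), 200L)
  sets <- tapply(tr$id, tr$frame, function(x) paste(sort(x), collapse = ","))
  expect_equal(unique(as.character(sets)), "1,2")
  expect_equal(sd(tr$y[tr$id == 1]), 0, tolerance = 1.5)
  expect_equal(sd(tr$y[tr$id == 2]), 0, tolerance = 1.5)
})

test_that("every non-Hough detection carries quality -1 through tracking", {
  cs <- problem_case(6)
  out <- apply_adhoc(cs$dets, cs$cfg, 90)
  introduced <- out$accepted$corrected
  expect_true(all(out$accepted$quality[introduced] == -1))
  expect_true(all(out$accepted$quality[!introduced] >= 0.3))
})
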