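#' Correction configuration
#'
#' Parameters for the within-frame (ad-hoc) and across-frame (post-hoc)
#' correction stages.
#'
#' @param n_animals number of animals the user expects in the scene.
#' @param overlap_frac fraction of mutual surface-area overlap
#'   (intersection over the smaller ellipse area) above which two
#'   detections count as "overlaying" (default 0.5).
#' @param chain_factor size ratio above which a detection counts as a
#'   chain of animals (default 1.5 x the expected single-animal size).
#' @param weights named numeric vector `c(pos=, surf=, cont=)` in \[0,1\]
#'   weighting the position, surface and contour estimators of the
#'   post-hoc stage; a zero weight omits that estimator.
#' @return An object of class `correction_config`.
#' @export
correction_config <- function(n_animals = 1L, overlap_frac = 0.5,
                              chain_factor = 1.5,
                              weights = c(pos = 1, surf = 0.5, cont = 0.5)) {
  if (n_animals < 1L) stop("n_animals must be >= 1", call. = FALSE)
  if (!(overlap_frac > 0 && overlap_frac < 1))
    stop("overlap_frac must lie in (0,1)", call. = FALSE)
  if (chain_factor <= 1) stop("chain_factor must exceed 1", call. = FALSE)
  w <- c(pos = 0, surf = 0, cont = 0)
  w[names(weights)] <- weights
  if (all(w <= 0)) stop("at least one estimator weight must be > 0",
                        call. = FALSE)
  structure(list(n_animals = as.integer(n_animals),
                 overlap_frac = overlap_frac, chain_factor = chain_factor,
                 weights = w),
            class = "correction_config")
}

det_columns <- c("x", "y", "a", "b", "theta", "quality")

empty_detections <- function() {
  data.frame(x = numeric(0), y = numeric(0), a = numeric(0), b = numeric(0),
             theta = numeric(0), quality = numeric(0),
             orig_quality = numeric(0), corrected = logical(0))
}

as_accepted <- function(df, corrected = FALSE) {
  if (NROW(df) == 0L) return(empty_detections())
  out <- df[, det_columns, drop = FALSE]
  out$orig_quality <- if ("orig_quality" %in% names(df)) df$orig_quality else
    df$quality
  out$corrected <- if ("corrected" %in% names(df)) df$corrected else corrected
  out$quality[out$corrected] <- -1
  rownames(out) <- NULL
  out
}

#' Per-frame detection container
#'
#' @param frame frame index.
#' @param candidates data.frame from [detect_ellipses()] (columns
#'   `x,y,a,b,theta,quality,subthreshold`).
#' @param params a [detection_params] used to split accepted from
#'   sub-threshold candidates.
#' @return `frame_detections` object: `frame`, `accepted` (supra-threshold,
#'   columns plus `orig_quality`, `corrected`), `subthreshold` (sorted by
#'   descending quality, capped at `max_subthreshold_kept`),
#'   `problem_code` (0 until classified) and `unresolved` flag.
#' @export
frame_detections <- function(frame, candidates, params) {
  if (NROW(candidates) == 0L) {
    acc <- empty_detections()
    sub <- empty_detections()[, det_columns]
  } else {
    candidates <- candidates[order(-candidates$quality), , drop = FALSE]
    acc <- as_accepted(candidates[!candidates$subthreshold, , drop = FALSE])
    sub <- candidates[candidates$subthreshold, det_columns, drop = FALSE]
    sub <- head(sub, params$max_subthreshold_kept)
    rownames(sub) <- NULL
  }
  structure(list(frame = frame, accepted = acc, subthreshold = sub,
                 problem_code = 0L, unresolved = FALSE),
            class = "frame_detections")
}

# pairwise overlay matrix (intersection-over-min >= overlap_frac)
overlay_pairs <- function(acc, overlap_frac) {
  n <- nrow(acc)
  ov <- matrix(FALSE, n, n)
  if (n < 2L) return(ov)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    iom <- ellipse_iom(acc[i, ], acc[j, ])
    ov[i, j] <- ov[j, i] <- iom >= overlap_frac
  }
  ov
}

is_oversized <- function(acc, cfg, expected_size) {
  2 * acc$a >= cfg$chain_factor * expected_size
}

#' Classify the occlusion problem of a frame
#'
#' Compares the accepted detections against the user's animal-count prior
#' and returns the applicable standard problem code:
#' 0 none; 1 surplus, all explained by overlaying detections; 2 surplus,
#' none overlaying; 3 both; 4 deficit without oversized detections;
#' 5 deficit with an oversized detection whose splitting can restore the
#' count ("chaining"); 6 chaining whose splitting still leaves a deficit;
#' 7 correct count but chaining present.
#'
#' @param dets a [frame_detections].
#' @param cfg a [correction_config].
#' @param expected_size expected full major-axis length of one animal in px
#'   (see [expected_major()]).
#' @return integer problem code 0--7.
#' @export
classify_problem <- function(dets, cfg, expected_size) {
  acc <- dets$accepted
  n_acc <- nrow(acc)
  n <- cfg$n_animals
  over <- is_oversized(acc, cfg, expected_size)
  if (n_acc > n) {
    ov <- overlay_pairs(acc, cfg$overlap_frac)
    g <- igraph::graph_from_adjacency_matrix(ov, mode = "undirected")
    comp <- igraph::components(g)
    overlap_excess <- sum(pmax(0, comp$csize - 1))
    surplus <- n_acc - n
    if (overlap_excess == 0L) return(2L)
    if (overlap_excess >= surplus) return(1L)
    return(3L)
  }
  if (n_acc < n) {
    if (!any(over)) return(4L)
    k_extra <- sum(pmax(2, round(2 * acc$a[over] / expected_size)) - 1)
    if (n_acc + k_extra >= n) return(5L) else return(6L)
  }
  if (any(over)) return(7L)
  0L
}

#' Split a chained (oversized) detection into single animals
#'
#' Two animals aligned end-to-end can be mis-fitted as one oversized
#' ellipse. The oversized detection is replaced by
#' `k = round(major / expected major)` ellipses of the expected mean size,
#' evenly spaced along the detected major axis, inheriting the minor axis
#' and orientation and flagged as corrected (quality -1).
#'
#' @param det one-row detection data.frame.
#' @param params a [detection_params].
#' @param chain_factor ratio defining a chain (default 1.5).
#' @return data.frame of k >= 2 detections with `quality = -1`.
#' @export
split_chain <- function(det, params, chain_factor = 1.5) {
  exp_major <- expected_major(params)
  if (2 * det$a < chain_factor * exp_major)
    stop("contract error: detection is not oversized", call. = FALSE)
  full <- 2 * det$a
  k <- max(2L, as.integer(round(full / exp_major)))
  th <- det$theta * pi / 180
  off <- (seq_len(k) - (k + 1) / 2) * full / k
  out <- data.frame(x = det$x + off * cos(th), y = det$y + off * sin(th),
                    a = exp_major / 2, b = det$b, theta = det$theta,
                    quality = -1,
                    orig_quality = if ("orig_quality" %in% names(det))
                      det$orig_quality else det$quality,
                    corrected = TRUE)
  rownames(out) <- NULL
  out
}

# quality used to rank deletions: corrected detections fall back on the
# quality of the detection they came from
effective_quality <- function(acc) {
  ifelse(acc$corrected, acc$orig_quality, acc$quality)
}

#' Apply the within-frame correction rules
#'
#' Iteratively classifies the frame and applies the matching rule until the
#' accepted count equals the animal-count prior or no rule can make
#' progress: overlaying surplus detections lose their lowest-quality
#' members first, then remaining surplus is deleted globally by lowest
#' quality; deficits are filled from the sub-threshold list by descending
#' quality; oversized detections are split via [split_chain()] and counts
#' reconciled. Every detection a rule introduces carries quality -1.
#'
#' @param dets a [frame_detections].
#' @param cfg a [correction_config].
#' @param expected_size expected full major-axis length in px.
#' @return The corrected [frame_detections]; `problem_code` records the
#'   first non-zero classification, `unresolved` is set when no candidates
#'   remain to reach the prior.
#' @export
apply_adhoc <- function(dets, cfg, expected_size) {
  n <- cfg$n_animals
  first_code <- 0L
  for (iter in 1:8) {
    code <- classify_problem(dets, cfg, expected_size)
    if (first_code == 0L) first_code <- code
    if (code == 0L) break
    acc <- dets$accepted
    if (code %in% c(1L, 3L)) {
      # delete lowest-quality members of overlaying groups
      while (nrow(acc) > n) {
        ov <- overlay_pairs(acc, cfg$overlap_frac)
        inv <- which(rowSums(ov) > 0)
        if (length(inv) == 0L) break
        drop <- inv[which.min(effective_quality(acc)[inv])]
        acc <- acc[-drop, , drop = FALSE]
      }
      dets$accepted <- acc
      if (code == 1L || nrow(acc) <= n) next
      code <- 2L
    }
    if (code == 2L) {
      while (nrow(acc) > n)
        acc <- acc[-which.min(effective_quality(acc)), , drop = FALSE]
      dets$accepted <- acc
      next
    }
    if (code %in% c(5L, 6L, 7L)) {
      over <- which(is_oversized(acc, cfg, expected_size))
      if (length(over) > 0L) {
        kids <- do.call(rbind, lapply(over, function(i)
          split_chain(acc[i, ],
                      list(min_major = expected_size, max_major = expected_size),
                      cfg$chain_factor)))
        acc <- rbind(acc[-over, , drop = FALSE], as_accepted(kids))
      }
      # reconcile a surplus created by splitting
      while (nrow(acc) > n)
        acc <- acc[-which.min(effective_quality(acc)), , drop = FALSE]
      dets$accepted <- acc
      if (nrow(acc) >= n) next
      code <- 4L
    }
    if (code == 4L) {
      while (nrow(dets$accepted) < n && nrow(dets$subthreshold) > 0L) {
        best <- which.max(dets$subthreshold$quality)
        dets$accepted <- rbind(dets$accepted,
                               as_accepted(dets$subthreshold[best, ],
                                           corrected = TRUE))
        dets$subthreshold <- dets$subthreshold[-best, , drop = FALSE]
      }
      if (nrow(dets$accepted) < n) { dets$unresolved <- TRUE; break }
    }
  }
  dets$problem_code <- first_code
  rownames(dets$accepted) <- NULL
  dets
}

# mean reference (position, area, perimeter) from neighbouring frames
reference_for <- function(cand, prev_acc, next_acc) {
  pick <- function(acc) {
    d <- sqrt((acc$x - cand$x)^2 + (acc$y - cand$y)^2)
    acc[which.min(d), ]
  }
  refs <- list()
  if (NROW(prev_acc) > 0L) refs <- c(refs, list(pick(prev_acc)))
  if (NROW(next_acc) > 0L) refs <- c(refs, list(pick(next_acc)))
  if (length(refs) == 0L) return(NULL)
  list(x = mean(vapply(refs, `[[`, numeric(1), "x")),
       y = mean(vapply(refs, `[[`, numeric(1), "y")),
       area = mean(vapply(refs, function(r) pi * r$a * r$b, numeric(1))),
       perim = mean(vapply(refs, function(r) ellipse_perimeter(r$a, r$b),
                           numeric(1))))
}

#' Rescue a deficit frame from its neighbours
#'
#' Scores the remaining sub-threshold candidates of a frame against the
#' accepted detections of the previous and next frames with three bounded
#' estimators — position `1/(1 + d/d0)` with `d0` the expected major axis,
#' surface `min/max` ratio of ellipse areas, contour `min/max` ratio of
#' ellipse perimeters — combined as the weighted mean over the estimators
#' with positive weight. The best-scoring candidate is accepted with
#' quality -1; exact ties go to the higher raw detection quality, then the
#' lower candidate index.
#'
#' @param prev,nxt neighbouring [frame_detections] (either may be `NULL`
#'   at the sequence ends).
#' @param cur the deficit [frame_detections].
#' @param cfg a [correction_config].
#' @param expected_size expected full major-axis length in px.
#' @return The updated [frame_detections] for the current frame.
#' @export
posthoc_rescue <- function(prev, cur, nxt, cfg, expected_size) {
  n <- cfg$n_animals
  w <- cfg$weights
  prev_acc <- if (is.null(prev)) empty_detections() else prev$accepted
  next_acc <- if (is.null(nxt)) empty_detections() else nxt$accepted
  while (nrow(cur$accepted) < n && nrow(cur$subthreshold) > 0L) {
    sub <- cur$subthreshold
    scores <- vapply(seq_len(nrow(sub)), function(i) {
      cand <- sub[i, ]
      ref <- reference_for(cand, prev_acc, next_acc)
      if (is.null(ref)) return(cand$quality)  # no neighbours: raw quality
      s <- c(pos = 0, surf = 0, cont = 0)
      d <- sqrt((cand$x - ref$x)^2 + (cand$y - ref$y)^2)
      s["pos"] <- 1 / (1 + d / expected_size)
      ca <- pi * cand$a * cand$b
      s["surf"] <- min(ca, ref$area) / max(ca, ref$area)
      cp <- ellipse_perimeter(cand$a, cand$b)
      s["cont"] <- min(cp, ref$perim) / max(cp, ref$perim)
      use <- w > 0
      sum(w[use] * s[use]) / sum(w[use])
    }, numeric(1))
    best <- which(scores > max(scores) - 1e-12)
    if (length(best) > 1L) {
      best <- best[order(-sub$quality[best], best)]
    }
    best <- best[1]
    cur$accepted <- rbind(cur$accepted,
                          as_accepted(sub[best, ], corrected = TRUE))
    cur$subthreshold <- sub[-best, , drop = FALSE]
    cur$unresolved <- nrow(cur$accepted) < n
  }
  rownames(cur$accepted) <- NULL
  cur
}

#' Minimum-cost assignment between consecutive frames
#'
#' Matches current detections to previous ones by minimizing the total
#' Euclidean center distance (Hungarian / LSAP solver). Surplus current
#' detections receive new identities.
#'
#' @param prev_xy m x 2 matrix of previous centers.
#' @param cur_xy k x 2 matrix of current centers.
#' @return integer vector of length k: for each current detection the index
#'   of its previous match, or `NA` for a new identity.
#' @export
assign_identities <- function(prev_xy, cur_xy) {
  m <- NROW(prev_xy); k <- NROW(cur_xy)
  if (m == 0L || k == 0L) return(rep(NA_integer_, k))
  prev_xy <- matrix(prev_xy, ncol = 2); cur_xy <- matrix(cur_xy, ncol = 2)
  cost <- outer(seq_len(m), seq_len(k), function(i, j)
    sqrt((prev_xy[i, 1] - cur_xy[j, 1])^2 + (prev_xy[i, 2] - cur_xy[j, 2])^2))
  out <- rep(NA_integer_, k)
  if (m <= k) {
    sol <- clue::solve_LSAP(cost)           # prev i -> cur sol[i]
    out[as.integer(sol)] <- seq_len(m)
  } else {
    sol <- clue::solve_LSAP(t(cost))        # cur j -> prev sol[j]
    out <- as.integer(sol)
  }
  out
}

#' Track a detected video: corrections, rescue and identity assignment
#'
#' Runs [apply_adhoc()] on every frame, a post-hoc rescue sweep over frames
#' still short of the animal-count prior, and frame-to-frame identity
#' assignment by minimum-cost matching.
#'
#' @param det_list list of [frame_detections], one per frame in order.
#' @param cfg a [correction_config].
#' @param params a [detection_params].
#' @return list with `track` (data.frame: frame, id, x, y, a, b, theta,
#'   quality, problem_code, corrected), `frames` (the corrected
#'   [frame_detections] list) and `summary` (fractions of corrected,
#'   accepted and unresolved frames).
#' @export
track_video <- function(det_list, cfg, params) {
  expected_size <- expected_major(params)
  det_list <- lapply(det_list, apply_adhoc, cfg = cfg,
                     expected_size = expected_size)
  nT <- length(det_list)
  for (i in seq_len(nT)) {
    if (nrow(det_list[[i]]$accepted) < cfg$n_animals) {
      det_list[[i]] <- posthoc_rescue(
        if (i > 1) det_list[[i - 1]] else NULL,
        det_list[[i]],
        if (i < nT) det_list[[i + 1]] else NULL,
        cfg, expected_size)
    }
  }
  rows <- list()
  prev_xy <- NULL; prev_ids <- integer(0); next_id <- 1L
  for (i in seq_len(nT)) {
    acc <- det_list[[i]]$accepted
    if (nrow(acc) == 0L) { prev_xy <- NULL; prev_ids <- integer(0); next }
    match_idx <- if (is.null(prev_xy)) rep(NA_integer_, nrow(acc)) else
      assign_identities(prev_xy, cbind(acc$x, acc$y))
    ids <- integer(nrow(acc))
    for (j in seq_len(nrow(acc))) {
      if (is.na(match_idx[j])) { ids[j] <- next_id; next_id <- next_id + 1L }
      else ids[j] <- prev_ids[match_idx[j]]
    }
    rows[[i]] <- data.frame(frame = det_list[[i]]$frame, id = ids,
                            x = acc$x, y = acc$y, a = acc$a, b = acc$b,
                            theta = acc$theta, quality = acc$quality,
                            problem_code = det_list[[i]]$problem_code,
                            corrected = acc$corrected)
    prev_xy <- cbind(acc$x, acc$y); prev_ids <- ids
  }
  track <- do.call(rbind, rows)
  n_acc <- vapply(det_list, function(d) nrow(d$accepted), integer(1))
  summary <- list(
    frac_corrected = mean(vapply(det_list, function(d)
      d$problem_code != 0L, logical(1))),
    frac_accepted = mean(n_acc >= cfg$n_animals),
    frac_any_detection = mean(n_acc >= 1L),
    frac_unresolved = mean(vapply(det_list, function(d) d$unresolved,
                                  logical(1))))
  list(track = track, frames = det_list, summary = summary)
}
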