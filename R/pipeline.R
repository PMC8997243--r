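#' Longest-processing-time greedy job balancing
#'
#' Assigns jobs (detection scripts with estimated durations) to CPU cores
#' by the classical LPT greedy: jobs sorted by decreasing duration, each
#' placed on the currently least-loaded core. The greedy makespan is within
#' 4/3 of the optimum.
#'
#' @param durations positive job durations in seconds.
#' @param n_cores number of cores (>= 1).
#' @return list with `assignment` (per-core integer vectors of job
#'   indices), `loads` (per-core total duration) and `makespan`.
#' @export
balance_jobs <- function(durations, n_cores) {
  stopifnot(n_cores >= 1, all(durations > 0))
  ord <- order(durations, decreasing = TRUE)
  assignment <- vector("list", n_cores)
  loads <- numeric(n_cores)
  for (j in ord) {
    core <- which.min(loads)
    assignment[[core]] <- c(assignment[[core]], j)
    loads[core] <- loads[core] + durations[j]
  }
  list(assignment = assignment, loads = loads, makespan = max(loads))
}

#' Pipeline configuration
#'
#' Collects every stage parameter of [run_pipeline()] in one object; can be
#' read from / written to YAML.
#'
#' @param min_major,max_major admissible full major-axis range, px.
#' @param n_animals expected number of animals.
#' @param fps frame rate override (Hz), needed for image-sequence input.
#' @param bg_mode temporal projection for the background (`"max"` for dark
#'   animals on bright ground, `"min"` for the inverse, `"mean"` for
#'   mildly varying illumination).
#' @param threshold binarization threshold (default 0.25).
#' @param erode_radius disk radius of the erosion step (default 1).
#' @param quality_threshold Hough quality acceptance threshold.
#' @param overlap_frac,chain_factor,weights see [correction_config()].
#' @param roi optional [roi].
#' @param min_area minimum component area; default `pi * (min_major/4)^2`.
#' @param n_seeds contour seeds for the pose stage (default 100).
#' @param smooth_frames moving-average width (frames) applied to positions
#'   and headings before differentiation (default 1 = off).
#' @param seed RNG seed used by the detection stage.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(min_major, max_major, n_animals = 1L,
                            fps = NULL, bg_mode = "max", threshold = 0.25,
                            erode_radius = 1L, quality_threshold = 0.3,
                            overlap_frac = 0.5, chain_factor = 1.5,
                            weights = c(pos = 1, surf = 0.5, cont = 0.5),
                            roi = NULL, min_area = NULL, n_seeds = 100L,
                            smooth_frames = 1L, seed = 1L) {
  if (is.null(min_area)) min_area <- pi * (min_major / 4)^2
  cfg <- list(min_major = min_major, max_major = max_major,
              n_animals = as.integer(n_animals), fps = fps,
              bg_mode = bg_mode, threshold = threshold,
              erode_radius = as.integer(erode_radius),
              quality_threshold = quality_threshold,
              overlap_frac = overlap_frac, chain_factor = chain_factor,
              weights = weights, roi = roi, min_area = min_area,
              n_seeds = as.integer(n_seeds),
              smooth_frames = as.integer(smooth_frames),
              seed = as.integer(seed))
  # validate the derived parameter objects early
  detection_params(min_major, max_major, n_animals, quality_threshold)
  correction_config(n_animals, overlap_frac, chain_factor, weights)
  structure(cfg, class = "pipeline_config")
}

#' Detect candidate ellipses in every frame
#'
#' Applies the six-step segmentation chain (difference image, normalize,
#' binarize, ROI, erode, boundary extraction) and runs the Hough detector
#' on each boundary's sub-image.
#'
#' @param seq a [frame_sequence].
#' @param bg a `background_image` from [compute_background()].
#' @param config a [pipeline_config].
#' @return list of [frame_detections] with an attribute `contours` holding
#'   the per-frame contour lists (for the pose stage).
#' @export
detect_sequence <- function(seq, bg, config) {
  params <- detection_params(config$min_major, config$max_major,
                             config$n_animals, config$quality_threshold)
  nT <- length(seq$frames)
  det_list <- vector("list", nT)
  contours_list <- vector("list", nT)
  for (t in seq_len(nT)) {
    diffi <- difference_image(seq$frames[[t]], bg)
    normi <- normalize_image(diffi)
    mask <- binarize(normi, config$threshold)
    mask <- apply_roi(mask, config$roi)
    mask <- erode_mask(mask, config$erode_radius)
    contours <- extract_boundaries(mask, min_area = config$min_area)
    contours_list[[t]] <- contours
    cand <- NULL
    if (length(contours) > 0L) {
      subs <- split_subimages(mask, contours)
      cand <- do.call(rbind, lapply(seq_along(subs), function(k) {
        d <- detect_ellipses(subs[[k]]$points, params,
                             rng_seed = config$seed + t)
        if (nrow(d) > 0L) {
          d$x <- d$x + subs[[k]]$offset[1]
          d$y <- d$y + subs[[k]]$offset[2]
        }
        d$contour_id <- rep(k, nrow(d))
        d
      }))
    }
    if (is.null(cand))
      cand <- data.frame(x = numeric(0), y = numeric(0), a = numeric(0),
                         b = numeric(0), theta = numeric(0),
                         quality = numeric(0), subthreshold = logical(0))
    det_list[[t]] <- frame_detections(t, cand, params)
  }
  attr(det_list, "contours") <- contours_list
  det_list
}

# contour containing (or nearest to) a detection center
match_contour <- function(det, contours) {
  if (length(contours) == 0L) return(NULL)
  for (ct in contours) {
    if (pracma::inpolygon(det$x, det$y, ct$points[, 1], ct$points[, 2],
                          boundary = TRUE))
      return(ct)
  }
  cent <- vapply(contours, function(ct) colMeans(ct$points), numeric(2))
  d <- (cent[1, ] - det$x)^2 + (cent[2, ] - det$y)^2
  contours[[which.min(d)]]
}

moving_average <- function(x, w) {
  if (w <= 1L || length(x) < w) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

#' Run the full tracking pipeline on a frame sequence
#'
#' Background projection, per-frame segmentation and Hough detection,
#' ad-hoc and post-hoc corrections, identity assignment, pose
#' (pseudo-skeleton) extraction, optional calibration and the kinematics
#' table.
#'
#' @param seq a [frame_sequence] (or a path handed to [open_frames()],
#'   requiring `config$fps`).
#' @param config a [pipeline_config].
#' @param cal optional [calibration].
#' @param out_dir optional output directory: writes `track.csv`,
#'   `skeletons.json` (JSON lines), `kinematics_<id>.csv` and
#'   `summary.json`.
#' @param stages how far to run: `"track"` stops after detection +
#'   corrections + identities, `"pose"` adds the pseudo-skeletons,
#'   `"kinematics"` (default) adds the kinematics tables.
#' @param verbose print per-stage progress.
#' @return list with `track`, `skeletons` (per track row), `kinematics`
#'   (list per identity), `summary`, `frames` (corrected detections) and
#'   `background`.
#' @export
run_pipeline <- function(seq, config, cal = NULL, out_dir = NULL,
                         stages = c("kinematics", "pose", "track"),
                         verbose = FALSE) {
  stages <- match.arg(stages)
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(seq)) seq <- open_frames(seq, fps_override = config$fps)
  stopifnot(inherits(seq, "frame_sequence"),
            inherits(config, "pipeline_config"))
  t0 <- proc.time()[3]
  bg <- compute_background(seq, mode = config$bg_mode)
  say("background (%s) from %d frames [%.1fs]", bg$mode, bg$n_frames_used,
      proc.time()[3] - t0)
  det_list <- detect_sequence(seq, bg, config)
  contours_list <- attr(det_list, "contours")
  say("detection done [%.1fs]", proc.time()[3] - t0)
  params <- detection_params(config$min_major, config$max_major,
                             config$n_animals, config$quality_threshold)
  cfg <- correction_config(config$n_animals, config$overlap_frac,
                           config$chain_factor, config$weights)
  tv <- track_video(det_list, cfg, params)
  track <- tv$track
  say("tracking done: %d rows, %.1f%% frames corrected [%.1fs]",
      NROW(track), 100 * tv$summary$frac_corrected, proc.time()[3] - t0)
  skeletons <- vector("list", NROW(track))
  if (stages != "track" && NROW(track) > 0L) {
    for (r in seq_len(nrow(track))) {
      ct <- match_contour(track[r, ], contours_list[[track$frame[r]]])
      skeletons[[r]] <- if (is.null(ct)) NULL else
        tryCatch(skeletonize(ct, n_seeds = config$n_seeds),
                 error = function(e) NULL)
    }
  }
  say("pose done [%.1fs]", proc.time()[3] - t0)
  kin <- list()
  if (stages == "kinematics" && NROW(track) > 0L) {
    for (id in sort(unique(track$id))) {
      sel <- which(track$id == id)
      if (length(sel) < 2L) next
      kin[[as.character(id)]] <-
        kinematics_table(track[sel, ], skeletons[sel], fps = seq$fps,
                         cal = cal, smooth_frames = config$smooth_frames)
    }
  }
  summary <- c(tv$summary,
               list(n_frames = length(seq$frames), n_track_rows = NROW(track),
                    n_identities = length(unique(track$id))))
  res <- list(track = track, skeletons = skeletons, kinematics = kin,
              summary = summary, frames = tv$frames,
              contours = contours_list, background = bg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(track, file.path(out_dir, "track.csv"),
                     row.names = FALSE)
    con <- file(file.path(out_dir, "skeletons.json"), "w")
    for (r in seq_along(skeletons)) {
      s <- skeletons[[r]]
      if (is.null(s)) next
      writeLines(jsonlite::toJSON(list(frame = track$frame[r],
                                       id = track$id[r],
                                       length_px = s$length_px,
                                       points = s$points),
                                  auto_unbox = TRUE, digits = NA), con)
    }
    close(con)
    for (id in names(kin))
      utils::write.csv(kin[[id]],
                       file.path(out_dir, sprintf("kinematics_%s.csv", id)),
                       row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Read / write a pipeline configuration as YAML
#' @param config a [pipeline_config].
#' @param path YAML file path.
#' @return `path` (write) or a [pipeline_config] (read).
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$roi <- if (is.null(config$roi)) NULL else
    list(shape = config$roi$shape,
         vertices = apply(config$roi$vertices, 1, as.numeric,
                          simplify = FALSE))
  x$weights <- as.list(config$weights)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  r <- if (is.null(y$roi)) NULL else
    roi(y$roi$shape, do.call(rbind, y$roi$vertices))
  pipeline_config(min_major = y$min_major, max_major = y$max_major,
                  n_animals = y$n_animals, fps = y$fps, bg_mode = y$bg_mode,
                  threshold = y$threshold, erode_radius = y$erode_radius,
                  quality_threshold = y$quality_threshold,
                  overlap_frac = y$overlap_frac,
                  chain_factor = y$chain_factor,
                  weights = unlist(y$weights), roi = r,
                  min_area = y$min_area, n_seeds = y$n_seeds,
                  smooth_frames = y$smooth_frames, seed = y$seed)
}
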