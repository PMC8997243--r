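# Background regimes for the synthetic scenes.
# "uniform" emulates contact-imaging footage: flat bright field, strong
# contrast, little sensor noise. "gradient" emulates a back-lit tank: a 20%
# linear illumination ramp, weak contrast and stronger pixel noise.
regime_defaults <- function(regime) {
  switch(regime,
    uniform  = list(base = 0.85, ramp = 0.00, contrast = 0.7, noise_sd = 0.005),
    gradient = list(base = 0.75, ramp = 0.20, contrast = 0.3, noise_sd = 0.02),
    stop("configuration error: unknown regime ", regime, call. = FALSE))
}

background_field <- function(H, W, base, ramp) {
  gx <- base * (1 + ramp * ((seq_len(W) - 1) / (W - 1) - 0.5))
  matrix(gx, H, W, byrow = TRUE)
}

# Render filled bodies with rounded, anti-aliased edges: each body is the
# set of pixels within the (per-segment) radius of its midline polyline.
render_bodies <- function(midlines, radii, H, W, bg, contrast, noise_sd) {
  img <- bg
  for (k in seq_along(midlines)) {
    ml <- midlines[[k]]
    r <- radii[[k]]
    if (length(r) == 1L) r <- rep(r, nrow(ml))
    rmax <- max(r)
    x0 <- max(0, floor(min(ml[, 1]) - rmax - 2))
    x1 <- min(W - 1, ceiling(max(ml[, 1]) + rmax + 2))
    y0 <- max(0, floor(min(ml[, 2]) - rmax - 2))
    y1 <- min(H - 1, ceiling(max(ml[, 2]) + rmax + 2))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    px <- rep(xs, each = length(ys))
    py <- rep(ys, times = length(xs))
    sdist <- rep(Inf, length(px))
    for (s in seq_len(nrow(ml) - 1L)) {
      ax <- ml[s, 1]; ay <- ml[s, 2]
      bx <- ml[s + 1, 1]; by <- ml[s + 1, 2]
      dx <- bx - ax; dy <- by - ay
      len2 <- dx * dx + dy * dy
      t <- if (len2 < 1e-12) rep(0, length(px)) else
        pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
      d <- sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
      rs <- r[s] + t * (r[s + 1] - r[s])
      sdist <- pmin(sdist, d - rs)
    }
    alpha <- pmin(1, pmax(0, 0.5 - sdist))
    sub <- img[ys + 1, xs + 1]
    sub <- sub - matrix(alpha, length(ys), length(xs)) * contrast
    img[ys + 1, xs + 1] <- sub
  }
  if (noise_sd > 0)
    img <- img + matrix(rnorm(H * W, 0, noise_sd), H, W)
  matrix(pmin(1, pmax(0, img)), H, W)
}

# constant-curvature arc of given length, tangent `heading` at its middle,
# centered (by centroid) at `center`; n points
bent_midline <- function(center, heading_rad, arc_len, bend_rad, n = 41L) {
  s <- seq(-arc_len / 2, arc_len / 2, length.out = n)
  psi <- heading_rad + bend_rad * s / arc_len
  ds <- arc_len / (n - 1L)
  x <- cumsum(c(0, (cos(psi[-n]) + cos(psi[-1])) / 2 * ds))
  y <- cumsum(c(0, (sin(psi[-n]) + sin(psi[-1])) / 2 * ds))
  pts <- cbind(x, y)
  sweep(pts, 2, colMeans(pts)) + matrix(center, n, 2, byrow = TRUE)
}

smooth_bump <- function(t, start, end) {
  u <- (t - start) / (end - start)
  ifelse(u > 0 & u < 1, sin(pi * u)^2, 0)
}

shift_into_frame <- function(centers, half_extent, margin) {
  lo <- apply(centers, 2, min) - half_extent
  centers <- sweep(centers, 2, lo - margin)
  size <- apply(centers, 2, max) + half_extent + margin
  list(centers = centers, W = ceiling(size[1]), H = ceiling(size[2]))
}

finish_scene <- function(midlines_list, radii_list, H, W, regime, contrast,
                         noise_sd, fps, truth) {
  rg <- regime_defaults(regime)
  if (is.null(contrast)) contrast <- rg$contrast
  if (is.null(noise_sd)) noise_sd <- rg$noise_sd
  bg <- background_field(H, W, rg$base, rg$ramp)
  frames <- lapply(seq_along(midlines_list), function(t)
    render_bodies(midlines_list[[t]], radii_list[[t]], H, W, bg, contrast,
                  noise_sd))
  truth$empty_background <- bg
  truth$regime <- regime
  truth$contrast <- contrast
  truth$noise_sd <- noise_sd
  list(seq = frame_sequence(frames, fps = fps, source_path = "<synthetic>"),
       truth = truth)
}

#' Synthetic crawling larva with programmed peristalsis and turns
#'
#' Renders a dark capsule-shaped crawler on a bright background. The
#' tip-to-tip body length oscillates sinusoidally with relative amplitude
#' `amplitude` percent (so `min/max = 1 - amplitude/100` by construction)
#' while the animal advances at constant speed; during scheduled turn
#' windows the midline bends into a C and the heading rotates. All motion
#' is deterministic given the seed; the seed also drives the pixel noise.
#'
#' @param n_frames frames to render (default 200).
#' @param fps frame rate (default 34 Hz, typical contact-imaging footage).
#' @param body_length tip-to-tip length at full extension, px (default 110).
#' @param body_width capsule width, px (default 14).
#' @param amplitude programmed contraction amplitude A* in percent
#'   (default 15, `0 <= A* < 60`).
#' @param period_s peristalsis period in seconds (default 1).
#' @param speed advance speed in px/frame (default 1.2).
#' @param turns list of turn events `list(start_s=, end_s=, angle_deg=)`.
#' @param regime `"uniform"` or `"gradient"` (see package vignette).
#' @param contrast,noise_sd override the regime presets.
#' @param margin frame margin around the trajectory, px.
#' @param seed RNG seed (drives initial heading jitter and pixel noise).
#' @return list with `seq` (a [frame_sequence]) and `truth` (per-frame
#'   `midline`, `center`, `heading_deg`, `body_length`, plus the event
#'   schedule, programmed amplitude, regime and the noise-free
#'   `empty_background`).
#' @export
make_crawler <- function(n_frames = 200L, fps = 34, body_length = 110,
                         body_width = 14, amplitude = 15, period_s = 1,
                         speed = 1.2, turns = list(), regime = "uniform",
                         contrast = NULL, noise_sd = NULL, margin = 30,
                         seed = 1L) {
  if (amplitude < 0 || amplitude >= 60)
    stop("configuration error: amplitude must lie in [0, 60)", call. = FALSE)
  set.seed(as.integer(seed))
  h0 <- runif(1, -20, 20) * pi / 180   # trajectory RNG before any noise
  tt <- (seq_len(n_frames) - 1) / fps
  turn_rate <- rep(0, n_frames)        # rad/frame
  bend <- rep(0, n_frames)             # rad, total midline bend
  for (ev in turns) {
    bump <- smooth_bump(tt, ev$start_s, ev$end_s)
    dur_frames <- (ev$end_s - ev$start_s) * fps
    rate <- deg2rad(ev$angle_deg) * bump / sum(bump)
    turn_rate <- turn_rate + ifelse(is.finite(rate), rate, 0)
    bend <- bend + deg2rad(ev$angle_deg) * bump * 0.9
  }
  heading <- h0 + cumsum(turn_rate)
  centers <- matrix(0, n_frames, 2)
  for (t in 2:n_frames)
    centers[t, ] <- centers[t - 1, ] +
      speed * c(cos(heading[t]), sin(heading[t]))
  sf <- shift_into_frame(centers, body_length / 2 + 2, margin)
  centers <- sf$centers
  L <- body_length * (1 - amplitude / 100 * (0.5 - 0.5 * cos(2 * pi * tt /
                                                              period_s)))
  midlines <- vector("list", n_frames)
  truth_mid <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    ml <- bent_midline(centers[t, ], heading[t], L[t] - body_width, bend[t])
    midlines[[t]] <- ml
    truth_mid[[t]] <- ml
    centers[t, ] <- colMeans(ml)
  }
  truth <- list(midline = truth_mid, center = centers,
                heading_deg = heading * 180 / pi, body_length = L,
                events = list(turns = turns), A_star = amplitude,
                body_width = body_width, fps = fps, seed = seed,
                scale_m_per_px = 5e-4)
  finish_scene(lapply(midlines, list),
               rep(list(list(body_width / 2)), n_frames),
               sf$H, sf$W, regime, contrast, noise_sd, fps, truth)
}

#' Synthetic swimming fish with programmed saccades and thrust strokes
#'
#' Renders a tapered fish silhouette following an intermittent burst-glide
#' trajectory: thrust events inject forward speed that decays exponentially
#' (glide), saccades inject Gaussian yaw-velocity pulses, and a travelling
#' body wave bends the midline. The truth records the schedules with their
#' programmed peaks, so pipeline detections can be validated against them.
#'
#' @param n_frames frames (default 200).
#' @param fps frame rate (default 200 Hz, high-speed tank footage).
#' @param body_length fish length, px (default 80).
#' @param body_width maximal body width, px (default 12).
#' @param undulation_amp lateral wave amplitude as a fraction of body
#'   length (default 0.05).
#' @param undulation_freq body-wave frequency in Hz (default 6).
#' @param initial_speed starting speed in m/s (default 0.05).
#' @param glide_tau_s exponential glide decay constant in s (default 0.25).
#' @param saccades list of `list(time_s=, peak_deg_s=)` yaw pulses.
#' @param thrusts list of `list(time_s=, peak_m_s=)` speed impulses.
#' @param scale_m_per_px pixel pitch of the virtual camera (default 5e-4,
#'   i.e. 0.5 mm/px).
#' @param regime,contrast,noise_sd,margin,seed as in [make_crawler()].
#' @return list `(seq, truth)` as in [make_crawler()].
#' @export
make_swimmer <- function(n_frames = 200L, fps = 200, body_length = 80,
                         body_width = 12, undulation_amp = 0.05,
                         undulation_freq = 6, initial_speed = 0.05,
                         glide_tau_s = 0.25, saccades = list(),
                         thrusts = list(), scale_m_per_px = 5e-4,
                         regime = "uniform", contrast = NULL,
                         noise_sd = NULL, margin = 30, seed = 1L) {
  set.seed(as.integer(seed))
  h0 <- runif(1, 0, 360) * pi / 180
  tt <- (seq_len(n_frames) - 1) / fps
  px_per_frame <- function(v_ms) v_ms / scale_m_per_px / fps
  speed <- px_per_frame(initial_speed) * exp(-tt / glide_tau_s)
  for (ev in thrusts) {
    dt <- tt - ev$time_s
    speed <- speed + px_per_frame(ev$peak_m_s) * ifelse(dt >= 0,
                                                        exp(-dt / glide_tau_s), 0)
  }
  yaw_vel <- rep(0, n_frames)   # deg/s
  for (ev in saccades)
    yaw_vel <- yaw_vel + ev$peak_deg_s * exp(-((tt - ev$time_s) / 0.04)^2)
  heading <- h0 + cumsum(deg2rad(yaw_vel)) / fps
  centers <- matrix(0, n_frames, 2)
  for (t in 2:n_frames)
    centers[t, ] <- centers[t - 1, ] +
      speed[t] * c(cos(heading[t]), sin(heading[t]))
  sf <- shift_into_frame(centers, body_length / 2 + 2, margin)
  centers <- sf$centers
  m <- 41L
  u <- seq(-0.5, 0.5, length.out = m)          # head at u = +0.5
  taper <- 0.5 * body_width * (1 - abs(2 * u)^2.5)^(1 / 1.6)
  midlines <- vector("list", n_frames)
  blen <- numeric(n_frames)
  for (t in seq_len(n_frames)) {
    dirv <- c(cos(heading[t]), sin(heading[t]))
    perp <- c(-dirv[2], dirv[1])
    lat <- undulation_amp * body_length * (0.5 - u) *
      sin(2 * pi * (1.5 * u - undulation_freq * tt[t]))
    ml <- matrix(centers[t, ], m, 2, byrow = TRUE) +
      outer(u * body_length, dirv) + outer(lat, perp)
    midlines[[t]] <- ml
    blen[t] <- sum(sqrt(rowSums(diff(ml)^2)))
    centers[t, ] <- colMeans(ml)
  }
  truth <- list(midline = midlines, center = centers,
                heading_deg = heading * 180 / pi, body_length = blen,
                speed_px = speed, yaw_velocity = yaw_vel,
                events = list(saccades = saccades, thrusts = thrusts),
                body_width = body_width, fps = fps, seed = seed,
                scale_m_per_px = scale_m_per_px)
  radii <- rep(list(list(taper)), n_frames)
  finish_scene(lapply(midlines, list), radii, sf$H, sf$W, regime, contrast,
               noise_sd, fps, truth)
}

#' Synthetic multi-animal scene with occlusion and chaining events
#'
#' Renders `n` crawlers on parallel tracks. During a chaining window two
#' animals align end-to-end (the "figure eight" mis-detection case); during
#' a crossing window one animal cuts across another's path so their
#' silhouettes overlap.
#'
#' @param n number of animals (>= 2).
#' @param n_frames,fps,body_length,body_width,speed as in [make_crawler()].
#' @param spacing distance between the parallel tracks, px.
#' @param chain_windows list of `c(start_frame, end_frame)` (1-based) during
#'   which animals 1 and 2 chain.
#' @param chain_overlap_px how deeply the two bodies interpenetrate along
#'   the shared axis while chained (default 18 px), so the union spans
#'   `2 * body_length - chain_overlap_px` tip to tip.
#' @param cross_windows list of `c(start_frame, end_frame)` during which
#'   animal 2 crosses animal 1's track.
#' @param regime,contrast,noise_sd,margin,seed as in [make_crawler()].
#' @return list `(seq, truth)`; truth holds per-animal midlines/centers and
#'   the window schedules.
#' @export
make_multianimal <- function(n = 2L, n_frames = 150L, fps = 34,
                             body_length = 90, body_width = 12, speed = 1.2,
                             spacing = 70, chain_windows = list(),
                             chain_overlap_px = 18, cross_windows = list(),
                             regime = "uniform",
                             contrast = NULL, noise_sd = NULL, margin = 30,
                             seed = 1L) {
  stopifnot(n >= 2L)
  set.seed(as.integer(seed))
  in_window <- function(t, windows)
    any(vapply(windows, function(w) t >= w[1] && t <= w[2], logical(1)))
  base_y <- (seq_len(n) - 1) * spacing
  centers <- array(0, c(n_frames, 2, n))
  heading <- matrix(0, n_frames, n)
  for (k in seq_len(n)) {
    centers[, 1, k] <- (seq_len(n_frames) - 1) * speed
    centers[, 2, k] <- base_y[k]
  }
  arc <- body_length - body_width
  for (t in seq_len(n_frames)) {
    if (in_window(t, chain_windows)) {
      # animal 2 docks end-to-end behind animal 1 (figure-eight union)
      centers[t, , 2] <- centers[t, , 1] - c(body_length - chain_overlap_px, 0)
      heading[t, 2] <- 0
    } else if (in_window(t, cross_windows)) {
      w <- Filter(function(w) t >= w[1] && t <= w[2], cross_windows)[[1]]
      u <- (t - w[1]) / max(1, w[2] - w[1])
      centers[t, , 2] <- c(centers[t, 1, 1],
                           centers[t, 2, 1] + (0.5 - u) * 1.2 * body_width)
      heading[t, 2] <- pi / 2
    }
  }
  all_c <- do.call(rbind, lapply(seq_len(n), function(k) centers[, , k]))
  lo <- apply(all_c, 2, min) - body_length / 2 - 2
  size <- apply(all_c, 2, max) - lo + body_length / 2 + 2 + 2 * margin
  midlines <- vector("list", n_frames)
  truth_mid <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    mls <- lapply(seq_len(n), function(k)
      bent_midline(centers[t, , k] - lo + margin, heading[t, k], arc, 0))
    midlines[[t]] <- mls
    truth_mid[[t]] <- mls
  }
  truth_centers <- lapply(seq_len(n), function(k)
    t(vapply(truth_mid, function(mls) colMeans(mls[[k]]), numeric(2))))
  truth <- list(midline = truth_mid, center = truth_centers,
                heading_deg = heading * 180 / pi,
                body_length = rep(body_length, n_frames),
                events = list(chain_windows = chain_windows,
                              cross_windows = cross_windows),
                n_animals = n, body_width = body_width, fps = fps,
                seed = seed, scale_m_per_px = 5e-4)
  radii <- rep(list(rep(list(body_width / 2), n)), n_frames)
  finish_scene(midlines, radii, ceiling(size[2]), ceiling(size[1]),
               regime, contrast, noise_sd, fps, truth)
}
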