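#' Peristaltic contraction amplitude
#'
#' `A = (1 - min(length) / max(length)) * 100` over the analysed interval:
#' the percentage by which the body mid-line shortens at the deepest point
#' of the peristaltic cycle relative to full extension.
#'
#' @param lengths numeric vector of body mid-line lengths (>= 2 samples,
#'   all positive), typically Dijkstra path lengths over a forward-crawl
#'   interval.
#' @return amplitude in percent, in \[0, 100).
#' @export
contraction_amplitude <- function(lengths) {
  if (length(lengths) < 2L || any(!is.finite(lengths)) || any(lengths <= 0))
    stop("contract error: need >= 2 positive body lengths", call. = FALSE)
  (1 - min(lengths) / max(lengths)) * 100
}

#' Signed curvature index of a pseudo-skeleton
#'
#' The skeleton is resampled to `n_points` equidistant points, translated
#' so its first point is at the origin and rotated so both endpoints have
#' x = 0 (the end-to-end axis becomes the y axis). With `I_abs` the
#' trapezoidal integral of |x-offset| — the lateral coordinate `y` in the
#' rotated frame — over the point index and `I` the signed integral, the
#' printed-form index is
#' `c = (I_abs - I) * (-sign(y_mid))` where `y_mid` is the lateral
#' coordinate of the middle point. A straight skeleton gives 0; a C-bend
#' gives a large |c| whose sign encodes the turn direction; an s-shape
#' yields cancelling signed area. Note the printed form is asymmetric: a
#' bend lying entirely on the positive lateral side gives `I_abs - I = 0`.
#' `variant = "symmetric"` instead returns the mirror-symmetric pair
#' `s_shape = I_abs - |I|` and `turn = |I| * sign(y_mid)` (not the printed
#' form; provided for convenience).
#'
#' @param skel a `pseudo_skeleton` or m x 2 point chain.
#' @param n_points resampling resolution (default 101).
#' @param variant `"printed"` (default) or `"symmetric"`.
#' @return For `"printed"` a single signed number (px^2 in index units);
#'   for `"symmetric"` a named vector `c(s_shape=, turn=)`.
#' @export
curvature_index <- function(skel, n_points = 101L, variant = c("printed",
                                                               "symmetric")) {
  variant <- match.arg(variant)
  pts <- if (inherits(skel, "pseudo_skeleton")) skel$points else skel
  if (NROW(pts) < 3L)
    stop("contract error: need >= 3 skeleton points", call. = FALSE)
  r <- resample_polyline(pts, n_points)
  r <- sweep(r, 2, r[1, ])
  v <- r[nrow(r), ]
  phi <- atan2(v[2], v[1])
  rot <- pi / 2 - phi                     # end-to-end vector -> +y axis
  lat <- r[, 1] * cos(rot) - r[, 2] * sin(rot)  # both endpoints at lat == 0
  idx <- seq_len(n_points) - 1
  I_abs <- pracma::trapz(idx, abs(lat))
  I <- pracma::trapz(idx, lat)
  mid <- lat[ceiling(n_points / 2)]
  s_mid <- sign(mid)
  if (variant == "printed") return((I_abs - I) * (-s_mid))
  c(s_shape = I_abs - abs(I), turn = abs(I) * s_mid)
}

#' Detect turning intervals from a curvature-index series
#'
#' Intervals where `|c|` exceeds `threshold` for at least `min_duration`
#' consecutive frames; intervals separated by gaps shorter than
#' `gap_frames` are merged.
#'
#' @param c_series numeric curvature-index series.
#' @param threshold positive threshold on `|c|`.
#' @param min_duration minimum interval length in frames (default 3).
#' @param gap_frames merge gaps shorter than this many frames (default 2).
#' @return data.frame with columns `start`, `end` (frame indices, 1-based,
#'   inclusive); zero rows if no turning.
#' @export
detect_turns <- function(c_series, threshold, min_duration = 3L,
                         gap_frames = 2L) {
  stopifnot(threshold > 0)
  above <- abs(c_series) > threshold
  if (!any(above)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge across short gaps
  if (nrow(iv) > 1L) {
    merged <- iv[1, ]
    for (k in 2:nrow(iv)) {
      if (iv$start[k] - merged$end[nrow(merged)] - 1L < gap_frames)
        merged$end[nrow(merged)] <- iv$end[k]
      else merged <- rbind(merged, iv[k, ])
    }
    iv <- merged
  }
  iv[iv$end - iv$start + 1L >= min_duration, , drop = FALSE]
}

deg2rad <- function(x) x * pi / 180

# central differences with one-sided ends, per unit index
central_diff <- function(x) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  d <- numeric(n)
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  if (n > 2L) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d
}

# unwrap a degree series (remove 360-degree jumps)
unwrap_deg <- function(theta) {
  d <- diff(theta)
  d <- d - 360 * round(d / 360)
  theta[1] + c(0, cumsum(d))
}

#' Resolve axial ellipse orientations into directed headings
#'
#' The fitted ellipse orientation is axial (defined mod 180 degrees). It is
#' resolved to a directed heading by aligning it with the instantaneous
#' velocity (non-negative dot product); at near-zero speed the previous
#' flip state is kept (hysteresis). The result is unwrapped.
#'
#' @param theta_deg axial orientations in degrees (continuous, i.e. already
#'   unwrapped mod 180).
#' @param positions T x 2 matrix of positions (same units throughout).
#' @param speed_eps speed below which the flip state is frozen, in position
#'   units per frame (default 0.05).
#' @param margin alignment hysteresis: the flip only toggles when the
#'   velocity contradicts the current heading by more than
#'   `acos(-margin)` (default 0.2, about 102 degrees), so lateral jitter
#'   near 90 degrees cannot toggle it.
#' @return directed, unwrapped headings in degrees.
#' @export
resolve_heading <- function(theta_deg, positions, speed_eps = 0.05,
                            margin = 0.2) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  vx <- central_diff(positions[, 1]); vy <- central_diff(positions[, 2])
  sp <- sqrt(vx^2 + vy^2)
  n <- length(theta_deg)
  out <- numeric(n)
  flip <- 0
  initialized <- FALSE
  for (t in seq_len(n)) {
    if (sp[t] > speed_eps) {
      h0 <- deg2rad(theta_deg[t] + flip)
      dotn <- (cos(h0) * vx[t] + sin(h0) * vy[t]) / sp[t]
      if (!initialized) {
        if (dotn < 0) flip <- flip + 180
        initialized <- TRUE
      } else if (dotn < -margin) {
        flip <- flip + 180
      }
    }
    out[t] <- theta_deg[t] + flip
  }
  unwrap_deg(out)
}

#' Ego-centric velocity decomposition
#'
#' Decomposes the translational velocity into thrust (component along the
#' heading) and slip (perpendicular component, positive to the left of the
#' heading), and differentiates the unwrapped heading into yaw velocity.
#' Derivatives are central differences (one-sided at the ends), scaled by
#' the frame rate. `thrust^2 + slip^2` equals the squared speed exactly.
#'
#' @param positions T x 2 matrix of positions in meters.
#' @param headings_deg directed headings in degrees (see
#'   [resolve_heading()]), unwrapped.
#' @param fps frame rate in Hz.
#' @return data.frame with `thrust`, `slip` (m/s), `yaw_velocity` (deg/s)
#'   and `speed` (m/s).
#' @export
ego_velocities <- function(positions, headings_deg, fps) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  stopifnot(nrow(positions) >= 2L, fps > 0)
  vx <- central_diff(positions[, 1]) * fps
  vy <- central_diff(positions[, 2]) * fps
  h <- deg2rad(headings_deg)
  thrust <- vx * cos(h) + vy * sin(h)
  slip <- -vx * sin(h) + vy * cos(h)
  yaw_velocity <- central_diff(headings_deg) * fps
  data.frame(thrust = thrust, slip = slip, yaw_velocity = yaw_velocity,
             speed = sqrt(vx^2 + vy^2))
}

#' Find threshold-exceeding peaks in a series
#'
#' Local maxima of `|series|` whose absolute value exceeds `threshold`,
#' separated by at least `min_separation` frames (the larger peak wins a
#' conflict). Used with the canonical thresholds of 200 deg/s on yaw
#' velocity (saccades) and 0.10 m/s on thrust velocity (thrust strokes).
#'
#' @param series numeric series.
#' @param threshold positive threshold on `|series|`.
#' @param min_separation minimum distance between events in frames.
#' @return integer vector of event indices (1-based).
#' @export
find_event_peaks <- function(series, threshold, min_separation = 1L) {
  stopifnot(threshold > 0)
  v <- abs(series)
  n <- length(v)
  if (n < 3L) return(integer(0))
  is_peak <- c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] &
                 v[2:(n - 1)] > v[3:n], FALSE) & v > threshold
  idx <- which(is_peak)
  if (length(idx) == 0L) return(integer(0))
  idx <- idx[order(-v[idx])]
  kept <- integer(0)
  for (i in idx) {
    if (all(abs(i - kept) >= min_separation)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Event-triggered average of a series
#'
#' Aligns windows `[-window, +window]` around each event and returns the
#' pointwise mean trace with a dispersion band: a bootstrap 95% confidence
#' interval of the pointwise median, or the standard deviation of the mean.
#' Events whose window would leave the series are dropped.
#'
#' @param series numeric series.
#' @param events integer event indices.
#' @param window half-window in frames.
#' @param band `"bootstrap_median"` or `"sd"`.
#' @param n_boot bootstrap replicates (default 200).
#' @param seed RNG seed for the bootstrap.
#' @return list with `lag` (frames, -window..window), `mean`, `lower`,
#'   `upper`, `n_events`; `NULL` if no complete window exists.
#' @export
triggered_average <- function(series, events, window,
                              band = c("bootstrap_median", "sd"),
                              n_boot = 200L, seed = 1L) {
  band <- match.arg(band)
  n <- length(series)
  events <- events[events - window >= 1 & events + window <= n]
  if (length(events) == 0L) return(NULL)
  lag <- -window:window
  mat <- vapply(events, function(e) series[e + lag],
                numeric(2 * window + 1))
  mat <- matrix(mat, nrow = 2 * window + 1)
  mu <- rowMeans(mat)
  if (band == "sd") {
    s <- apply(mat, 1, sd)
    lower <- mu - s; upper <- mu + s
  } else {
    k <- ncol(mat)
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(as.integer(seed))
    meds <- replicate(n_boot, {
      pick <- sample.int(k, k, replace = TRUE)
      apply(mat[, pick, drop = FALSE], 1, median)
    })
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    meds <- matrix(meds, nrow = 2 * window + 1)
    lower <- apply(meds, 1, quantile, 0.025)
    upper <- apply(meds, 1, quantile, 0.975)
  }
  list(lag = lag, mean = mu, lower = lower, upper = upper,
       n_events = length(events))
}

#' Event frequency
#' @param events event indices (any vector; only its length is used).
#' @param duration_s recording duration in seconds (> 0).
#' @return events per second (Hz).
#' @export
event_frequency <- function(events, duration_s) {
  stopifnot(duration_s > 0)
  length(events) / duration_s
}

#' Permutation test on the difference of medians
#'
#' Two-sided test with statistic `T = |median(A) - median(B)|` under the
#' null of exchangeability: pooled values are relabelled into groups of the
#' original sizes. With `exhaustive = TRUE` (or automatically when the
#' number of splits is at most `exhaustive_limit`) all C(n, nA) splits are
#' enumerated and the exact proportion with `T_perm >= T_obs` is returned;
#' otherwise `n_permutations` random relabelings are drawn and
#' `p = (#{T_perm >= T_obs} + 1) / (N + 1)`.
#'
#' @param a,b numeric vectors (each >= 1 value).
#' @param n_permutations random permutations when sampling (default 10000).
#' @param exhaustive force (`TRUE`) or forbid (`FALSE`) exhaustive
#'   enumeration; `NA` (default) enumerates when feasible.
#' @param exhaustive_limit largest number of splits enumerated when
#'   `exhaustive = NA` (default 20000).
#' @param seed RNG seed for the sampled variant.
#' @return p-value in (0, 1\].
#' @export
permutation_median_test <- function(a, b, n_permutations = 10000L,
                                    exhaustive = NA, exhaustive_limit = 20000L,
                                    seed = NULL) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  pool <- c(a, b)
  if (max(pool) - min(pool) < .Machine$double.eps) return(1)
  na <- length(a)
  t_obs <- abs(median(a) - median(b))
  n_splits <- choose(length(pool), na)
  do_exh <- isTRUE(exhaustive) ||
    (is.na(exhaustive) && n_splits <= exhaustive_limit)
  if (do_exh) {
    splits <- combn(length(pool), na)
    t_perm <- apply(splits, 2, function(idx)
      abs(median(pool[idx]) - median(pool[-idx])))
    return(mean(t_perm >= t_obs - 1e-12))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  hits <- 0L
  for (i in seq_len(n_permutations)) {
    idx <- sample.int(length(pool), na)
    if (abs(median(pool[idx]) - median(pool[-idx])) >= t_obs - 1e-12)
      hits <- hits + 1L
  }
  (hits + 1) / (n_permutations + 1)
}

#' Assemble the per-identity kinematics table
#'
#' Joins the track (ellipse detections) with the per-frame skeletons,
#' applies the calibration, resolves headings and computes the ego-centric
#' velocities, body length, bending angle, curvature index and
#' eccentricity. Body length is median-filtered over `length_filter`
#' frames to suppress single-frame skeletonization glitches.
#'
#' @param track data.frame from [track_video()] (one identity, or filtered
#'   to one id).
#' @param skeletons list of `pseudo_skeleton` (or `NULL`) aligned with the
#'   rows of `track`.
#' @param fps frame rate in Hz.
#' @param cal optional [calibration]; without it positions stay in px.
#' @param length_filter odd window for the running-median length filter
#'   (default 5; 1 disables).
#' @param k_segments segments for [bending_angle()] (default 10).
#' @param use_skeleton_position when a skeleton exists, take the body
#'   position as the centroid of the resampled mid-line instead of the
#'   ellipse center (default `TRUE`): the ellipse center of an undulating,
#'   tapered body is biased toward its wide end and oscillates with the
#'   body wave, while the mid-line centroid tracks the silhouette centroid.
#' @param smooth_frames moving-average window (frames) applied to positions
#'   and axial orientations before differentiation (default 1 = off);
#'   useful at high frame rates where differentiation amplifies pixel
#'   jitter.
#' @return data.frame with columns `frame, time_s, x, y, heading_deg,
#'   thrust, slip, yaw_velocity, speed, body_length, bending_angle,
#'   curvature_index, eccentricity`.
#' @export
kinematics_table <- function(track, skeletons, fps, cal = NULL,
                             length_filter = 5L, k_segments = 10L,
                             use_skeleton_position = TRUE,
                             smooth_frames = 1L) {
  stopifnot(nrow(track) >= 2L)
  pos_px <- cbind(track$x, track$y)
  theta_raw <- track$theta
  if (use_skeleton_position) {
    # the mid-line centroid tracks the silhouette centroid, and the
    # principal axis of the mid-line integrates the body wave out of the
    # orientation far better than the raw ellipse fit
    for (r in seq_along(skeletons)) {
      s <- skeletons[[r]]
      if (!is.null(s) && nrow(s$points) >= 3L) {
        rp <- resample_polyline(s$points, 51L)
        mu <- colMeans(rp)
        pos_px[r, ] <- mu
        xc <- rp[, 1] - mu[1]; yc <- rp[, 2] - mu[2]
        theta_raw[r] <- (0.5 * atan2(2 * sum(xc * yc),
                                     sum(xc^2) - sum(yc^2)) * 180 / pi) %% 180
      }
    }
  }
  theta <- unwrap_deg(theta_raw * 2) / 2     # continuous axial orientation
  if (smooth_frames > 1L) {
    pos_px[, 1] <- moving_average(pos_px[, 1], smooth_frames)
    pos_px[, 2] <- moving_average(pos_px[, 2], smooth_frames)
    theta <- moving_average(theta, smooth_frames)
  }
  pos <- if (is.null(cal)) pos_px else to_world(pos_px, cal)
  scale <- if (is.null(cal)) 1 else cal$scale
  heading <- resolve_heading(theta, pos_px, speed_eps = 0.05)
  ev <- ego_velocities(pos, heading, fps)
  blen <- vapply(skeletons, function(s)
    if (is.null(s)) NA_real_ else s$length_px, numeric(1)) * scale
  if (length_filter > 1L && sum(!is.na(blen)) > length_filter) {
    ok <- !is.na(blen)
    blen[ok] <- stats::runmed(blen[ok], k = length_filter, endrule = "keep")
  }
  bend <- vapply(skeletons, function(s) {
    if (is.null(s) || nrow(s$points) < 3L) return(NA_real_)
    bending_angle(s, k_segments)
  }, numeric(1))
  curv <- vapply(skeletons, function(s) {
    if (is.null(s) || nrow(s$points) < 3L) return(NA_real_)
    curvature_index(s)
  }, numeric(1))
  ecc <- sqrt(pmax(0, 1 - (track$b / track$a)^2))
  data.frame(frame = track$frame, time_s = (track$frame - min(track$frame)) / fps,
             x = pos[, 1], y = pos[, 2], heading_deg = heading,
             thrust = ev$thrust, slip = ev$slip,
             yaw_velocity = ev$yaw_velocity, speed = ev$speed,
             body_length = blen, bending_angle = bend,
             curvature_index = curv, eccentricity = ecc)
}

#' Detect saccades and thrust strokes from a kinematics table
#'
#' Applies the canonical event thresholds to the yaw-velocity and thrust
#' series: saccades are yaw-velocity peaks above 200 deg/s, thrust strokes
#' are thrust peaks above 10 cm/s, with a minimum peak separation of 0.1 s.
#'
#' @param kin a data.frame from [kinematics_table()].
#' @param fps frame rate in Hz.
#' @param saccade_threshold yaw-velocity threshold in deg/s (default 200).
#' @param thrust_threshold thrust threshold in m/s (default 0.10).
#' @param min_separation_s minimum separation between events in seconds
#'   (default 0.1).
#' @return list with `saccades`, `thrusts` (frame indices into `kin`),
#'   `saccade_frequency` and `thrust_frequency` (Hz).
#' @export
locomotion_events <- function(kin, fps, saccade_threshold = 200,
                              thrust_threshold = 0.10,
                              min_separation_s = 0.1) {
  sep <- max(1L, round(min_separation_s * fps))
  sac <- find_event_peaks(kin$yaw_velocity, saccade_threshold, sep)
  thr <- find_event_peaks(kin$thrust, thrust_threshold, sep)
  dur <- nrow(kin) / fps
  list(saccades = sac, thrusts = thr,
       saccade_frequency = event_frequency(sac, dur),
       thrust_frequency = event_frequency(thr, dur))
}
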