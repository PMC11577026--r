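#' Synthetic cohorts
#'
#' Seeded generator for two-mouse sessions with the statistical structure the
#' analysis assumes: a two-mode (roam/hide) correlated random walk on the
#' default arena, rank- and time-dependent ethogram event rates that ramp
#' linearly from parity at gate opening to full divergence by the late phase,
#' flight bouts with the assay's kinematic signature (speed peaking above
#' 50 cm/s within about a second of onset, against a sub-20 cm/s baseline),
#' and floor images bearing yellow and fuchsia mark patches of known area.
#' It exists to exercise every pipeline stage against planted ground truth;
#' it is not a behavioral model of the animals.
#'
#' @name synthetic
NULL

#' Specify a synthetic cohort
#'
#' Defaults emulate the study conditions: 120-min sessions at 45 fps with the
#' early/late 20-min observation phases, and a CD1-like divergence profile in
#' which the dominant's attack rate reaches 22.8 per 20 min in the late phase
#' while the subordinate stops attacking, flees and hides. `divergence` scales
#' the rank asymmetry: 0 gives a null cohort (parity throughout, like the
#' non-hierarchical inbred pairs), 1 full divergence. All rates are per
#' 20 min and ramp linearly from parity at t = 0 to their full split at
#' 100 min.
#'
#' @param n_pairs Number of pairs (>= 1).
#' @param session_min Session length, minutes (default 120).
#' @param frame_rate_hz Frame rate (default 45).
#' @param divergence Rank divergence `delta` in `[0, 1]` (default 1).
#' @param seed Cohort seed (integer).
#' @param attack_rate,chase_rate,flight_rate,upright_rate Length-2 numeric
#'   `c(base, div)`: a mouse's rate per 20 min is
#'   `max(0, base +/- ramp(t) * delta * div)` with `+` for the rank the
#'   behavior favors (dominant for attack/chase, subordinate for
#'   flight/upright).
#' @param hide_start_per_min,hide_duration_s Length-2 `c(base, div)` controls
#'   of the subordinate's hide-bout rate and mean duration.
#' @param roam_speed_cms Mean roaming speed (default 8, well under the
#'   20 cm/s baseline ceiling).
#' @param flight_peak_cms Peak flight speed (default 60, above the 50 cm/s
#'   signature).
#' @param mark_pct Length-2 `c(mid, div)`: marked-area percent is
#'   `mid +/- delta * div` for dominant/subordinate (defaults give 3% vs
#'   0.2% at full divergence).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pairs = 10, session_min = 120, frame_rate_hz = 45,
                        divergence = 1, seed = 1,
                        attack_rate = c(10, 12.8),
                        chase_rate = c(6, 8),
                        flight_rate = c(6, 10),
                        upright_rate = c(3, 3),
                        hide_start_per_min = c(0.05, 0.5),
                        hide_duration_s = c(20, 50),
                        roam_speed_cms = 8,
                        flight_peak_cms = 60,
                        mark_pct = c(1.6, 1.4)) {
  stopifnot(n_pairs >= 1, session_min > 40, frame_rate_hz > 0,
            divergence >= 0, divergence <= 1,
            all(c(attack_rate, chase_rate, flight_rate, upright_rate,
                  hide_start_per_min, hide_duration_s) >= 0),
            roam_speed_cms > 0, flight_peak_cms > 0)
  structure(list(n_pairs = as.integer(n_pairs), session_min = session_min,
                 frame_rate_hz = frame_rate_hz, divergence = divergence,
                 seed = as.integer(seed),
                 attack_rate = attack_rate, chase_rate = chase_rate,
                 flight_rate = flight_rate, upright_rate = upright_rate,
                 hide_start_per_min = hide_start_per_min,
                 hide_duration_s = hide_duration_s,
                 roam_speed_cms = roam_speed_cms,
                 flight_peak_cms = flight_peak_cms,
                 mark_pct = mark_pct),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d pairs, %g min @ %g fps, ",
                     "divergence %.2f, seed %d\n"),
              x$n_pairs, x$session_min, x$frame_rate_hz, x$divergence,
              x$seed))
  invisible(x)
}

# divergence ramp: 0 at t = 0, 1 from 100 min on
ramp_at <- function(t_s) pmin(1, t_s / 6000)

# rate per 20 min -> expected events in per-minute bins, rank-signed
minute_rates <- function(spec, rate, sign, n_min) {
  t_mid <- (seq_len(n_min) - 0.5) * 60
  pmax(0, rate[1] + sign * ramp_at(t_mid) * spec$divergence * rate[2]) / 20
}

# draw event onsets from per-minute expected counts
draw_onsets <- function(per_min) {
  onsets <- c()
  for (i in seq_along(per_min)) {
    k <- stats::rpois(1, per_min[i])
    if (k > 0) onsets <- c(onsets, (i - 1) * 60 + sort(stats::runif(k, 0, 60)))
  }
  onsets
}

# reflect coordinates into [lo, hi] (triangle fold)
fold_into <- function(v, lo, hi) {
  L <- hi - lo
  w <- (v - lo) %% (2 * L)
  lo + pmin(w, 2 * L - w)
}

# one correlated-random-walk segment of n frames from p0 within rect bounds;
# optional drift toward a point
crw_segment <- function(n, p0, bounds, speed_mean, fps, toward = NULL) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  base_heading <- if (is.null(toward)) stats::runif(1, 0, 2 * pi) else
    atan2(toward[2] - p0[2], toward[1] - p0[1])
  heading <- base_heading + cumsum(stats::rnorm(n, 0, 0.25))
  if (!is.null(toward))  # relax back toward the attraction heading
    heading <- base_heading + 0.8 * (heading - base_heading)
  sp <- stats::rgamma(n, shape = 16, rate = 16 / speed_mean)
  step <- sp / fps
  x <- fold_into(p0[1] + cumsum(step * cos(heading)), bounds[1], bounds[2])
  y <- fold_into(p0[2] + cumsum(step * sin(heading)), bounds[3], bounds[4])
  cbind(x, y)
}

# straight transit from p0 to p1 at roughly v cm/s; returns >= 1 frame
transit_segment <- function(p0, p1, v, fps) {
  d <- sqrt(sum((p1 - p0)^2))
  n <- max(1L, as.integer(ceiling(d / v * fps)))
  frac <- seq_len(n) / n
  cbind(p0[1] + frac * (p1[1] - p0[1]), p0[2] + frac * (p1[2] - p0[2]))
}

# triangular flight speed profile: rise to peak in ~0.5 s, decay by 1.2 s
flight_segment <- function(p0, peak, fps, bounds) {
  n <- as.integer(round(1.2 * fps))
  t <- seq_len(n) / fps
  sp <- ifelse(t <= 0.5, peak * t / 0.5, pmax(0, peak * (1 - (t - 0.5) / 0.7)))
  ang <- stats::runif(1, 0, 2 * pi)
  x <- fold_into(p0[1] + cumsum(sp * cos(ang)) / fps, bounds[1], bounds[2])
  y <- fold_into(p0[2] + cumsum(sp * sin(ang)) / fps, bounds[3], bounds[4])
  cbind(x, y)
}

# centers of the hiding ROIs of one compartment (corner ROIs only, so parked
# animals sit unambiguously inside a single refuge)
hide_spots <- function(layout, comp) {
  nms <- hiding_rois(layout)
  nms <- nms[vapply(layout$rois[nms], function(r)
    r$compartment_id == comp & r$category == "corner", TRUE)]
  t(vapply(layout$rois[nms], function(r) colMeans(r$polygon), numeric(2)))
}

# body-part offsets (cm) relative to the middle back, facing +x
PART_OFFSETS <- rbind(nose = c(4.5, 0), right_ear = c(3.2, 1.2),
                      left_ear = c(3.2, -1.2), middle_back = c(0, 0),
                      right_side = c(0, 1.8), left_side = c(0, -1.8),
                      tail_base = c(-3.5, 0), tail_end = c(-7.5, 0))

# expand an anchor path into an 8-part pose track with confidence dropouts
path_to_track <- function(path, mouse_id, fps, arena_wh) {
  n <- nrow(path)
  dx <- c(diff(path[, 1]), 0); dy <- c(diff(path[, 2]), 0)
  moving <- sqrt(dx^2 + dy^2) > 1e-6
  ang <- atan2(dy, dx)
  ang[!moving] <- NA
  # carry last heading through stationary stretches
  idx <- cummax(ifelse(moving, seq_len(n), 0L))
  ang <- ifelse(idx > 0L, ang[pmax(idx, 1L)], 0)
  parts <- rownames(PART_OFFSETS)
  xm <- matrix(0, n, length(parts), dimnames = list(NULL, parts))
  ym <- xm
  ca <- cos(ang); sa <- sin(ang)
  for (p in parts) {
    o <- PART_OFFSETS[p, ]
    xm[, p] <- path[, 1] + o[1] * ca - o[2] * sa + stats::rnorm(n, 0, 0.15)
    ym[, p] <- path[, 2] + o[1] * sa + o[2] * ca + stats::rnorm(n, 0, 0.15)
  }
  xm[] <- pmin(pmax(xm, 0), arena_wh[1])
  ym[] <- pmin(pmax(ym, 0), arena_wh[2])
  conf <- matrix(stats::rbeta(n * length(parts), 40, 2), n, length(parts),
                 dimnames = list(NULL, parts))
  # occasional short tracking dropouts
  n_drop <- max(1L, as.integer(n / 4000))
  starts <- sample.int(max(1L, n - 10L), n_drop)
  for (s in starts) {
    len <- 1L + stats::rgeom(1, 0.3)
    conf[s:min(n, s + len), sample(parts, 1L)] <- 0.05
  }
  pose_track(mouse_id, fps, xm, ym, conf)
}

# simulate one mouse's anchor path given its rank and schedules
simulate_path <- function(spec, layout, rank, own_comp, flights_s,
                          hide_bouts, opponent_path = NULL) {
  fps <- spec$frame_rate_hz
  n <- as.integer(spec$session_min * 60 * fps)
  arena <- c(0, layout$compartment_size_cm[1],
             0, 2 * layout$compartment_size_cm[2])
  own_bounds <- c(0, layout$compartment_size_cm[1],
                  (own_comp - 1) * layout$compartment_size_cm[2],
                  own_comp * layout$compartment_size_cm[2])
  spots <- hide_spots(layout, own_comp)
  # event timeline: hide bouts and flights as occupied intervals
  iv <- rbind(
    if (nrow(hide_bouts)) cbind(hide_bouts$start_s, hide_bouts$end_s, 1),
    if (length(flights_s)) cbind(flights_s, flights_s + 1.2, 2))
  if (is.null(iv)) iv <- matrix(numeric(0), 0, 3)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  # drop overlapping intervals (first wins)
  keep <- rep(TRUE, nrow(iv)); last_end <- -Inf
  for (i in seq_len(nrow(iv))) {
    if (iv[i, 1] < last_end) keep[i] <- FALSE else last_end <- iv[i, 2]
  }
  iv <- iv[keep, , drop = FALSE]
  path <- matrix(NA_real_, n, 2)
  p <- c(stats::runif(1, 20, 100),
         stats::runif(1, own_bounds[3] + 10, own_bounds[4] - 10))
  cursor <- 0L  # frames emitted
  emit <- function(seg) {
    m <- min(nrow(seg), n - cursor)
    if (m > 0L) path[(cursor + 1L):(cursor + m), ] <<- seg[seq_len(m), ]
    cursor <<- cursor + m
    if (m > 0L) p <<- seg[m, ]
  }
  roam_until <- function(end_frame) {
    while (cursor < end_frame) {
      d <- min(end_frame - cursor, as.integer(30 * fps))
      t_now <- cursor / fps
      confined <- rank == "subordinate" &&
        stats::runif(1) < ramp_at(t_now) * spec$divergence
      toward <- NULL
      if (!confined && rank == "subordinate" && !is.null(opponent_path) &&
          stats::runif(1) < 0.7 * (1 - ramp_at(t_now) * spec$divergence))
        toward <- opponent_path[min(nrow(opponent_path), cursor + 1L), ]
      bounds <- if (confined) own_bounds else arena
      if (p[2] < bounds[3] || p[2] > bounds[4])
        emit(transit_segment(p, c(p[1], mean(bounds[3:4])), 15, fps))
      if (cursor >= end_frame) break
      d <- min(end_frame - cursor, as.integer(30 * fps))
      emit(crw_segment(d, p, bounds, spec$roam_speed_cms, fps, toward))
    }
  }
  for (i in seq_len(nrow(iv))) {
    start_f <- as.integer(round(iv[i, 1] * fps))
    end_f <- min(n, as.integer(round(iv[i, 2] * fps)))
    if (start_f >= n) break
    roam_until(start_f)
    if (cursor >= end_f) next
    if (iv[i, 3] == 1) {  # hide: transit to a refuge, then park with jitter
      spot <- spots[sample.int(nrow(spots), 1L), ]
      emit(transit_segment(p, spot, 15, fps))
      d <- end_f - cursor
      if (d > 0L)
        emit(cbind(spot[1] + cumsum(stats::rnorm(d, 0, 0.02)),
                   spot[2] + cumsum(stats::rnorm(d, 0, 0.02))))
    } else {            # flight dash
      emit(flight_segment(p, spec$flight_peak_cms, fps, arena))
    }
  }
  roam_until(n)
  path
}

#' Simulate one mouse pair
#'
#' Generates the full record of one dyad: two pose tracks on the default
#' layout, a scored event table, and the planted ground truth (dominant
#' identity, flight and hide schedules, target marked-area percentages).
#' Identical seeds give bit-identical output.
#'
#' @param spec A [cohort_spec()].
#' @param pair_seed Integer seed for this pair.
#' @param pair_id Pair identifier (default `"pair1"`).
#' @param layout Arena layout (default [default_layout()]).
#' @return A list with `tracks` (named list of two [pose_track()]), `events`
#'   (an [ethogram_events()] table with `pair_id`), `truth` (list:
#'   `dominant`, `flights`, `hide_bouts`, `mark_pct`) and `layout`.
#' @export
simulate_pair <- function(spec, pair_seed, pair_id = "pair1",
                          layout = default_layout()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(pair_seed %% .Machine$integer.max)
  ids <- paste0(pair_id, c("_m1", "_m2"))
  dom_idx <- sample.int(2L, 1L)
  ranks <- if (dom_idx == 1L) c("dominant", "subordinate") else
    c("subordinate", "dominant")
  n_min <- as.integer(spec$session_min)
  fps <- spec$frame_rate_hz
  events <- list()
  flights_s <- list()
  hide_bouts <- list()
  for (i in 1:2) {
    sgn <- if (ranks[i] == "dominant") 1 else -1
    for (b in c("attack", "chase")) {
      rate <- if (b == "attack") spec$attack_rate else spec$chase_rate
      on <- draw_onsets(minute_rates(spec, rate, sgn, n_min))
      if (length(on))
        events[[length(events) + 1L]] <- data.frame(
          mouse_id = ids[i], behavior = b, onset_s = on,
          offset_s = on + stats::runif(length(on), 1, 4),
          pair_id = pair_id, stringsAsFactors = FALSE)
    }
    for (b in c("flight", "upright")) {
      rate <- if (b == "flight") spec$flight_rate else spec$upright_rate
      on <- draw_onsets(minute_rates(spec, rate, -sgn, n_min))
      if (b == "flight") flights_s[[i]] <- on
      if (length(on))
        events[[length(events) + 1L]] <- data.frame(
          mouse_id = ids[i], behavior = b, onset_s = on,
          offset_s = on + if (b == "flight") 1.2 else
            stats::runif(length(on), 1, 3),
          pair_id = pair_id, stringsAsFactors = FALSE)
    }
    # hide bouts: rate and duration grow with ramped divergence for the
    # subordinate, shrink (floored) for the dominant
    t_mid <- (seq_len(n_min) - 0.5) * 60
    g <- ramp_at(t_mid) * spec$divergence * ifelse(sgn == 1, -0.6, 1)
    p_start <- pmax(0, spec$hide_start_per_min[1] +
                      g * spec$hide_start_per_min[2])
    starts <- draw_onsets(p_start)
    if (length(starts)) {
      dur_mean <- pmax(5, spec$hide_duration_s[1] +
                         ramp_at(starts) * spec$divergence *
                         ifelse(sgn == 1, -0.5, 1) * spec$hide_duration_s[2])
      hide_bouts[[i]] <- data.frame(start_s = starts,
                                    end_s = starts + stats::rexp(
                                      length(starts), 1 / dur_mean))
    } else {
      hide_bouts[[i]] <- data.frame(start_s = numeric(0), end_s = numeric(0))
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(mouse_id = character(0), behavior = character(0),
               onset_s = numeric(0), offset_s = numeric(0),
               pair_id = character(0))
  events <- events[order(events$onset_s), ]
  rownames(events) <- NULL
  dom <- which(ranks == "dominant")
  sub <- 3L - dom
  paths <- list()
  paths[[dom]] <- simulate_path(spec, layout, "dominant", dom,
                                flights_s[[dom]], hide_bouts[[dom]])
  paths[[sub]] <- simulate_path(spec, layout, "subordinate", sub,
                                flights_s[[sub]], hide_bouts[[sub]],
                                opponent_path = paths[[dom]])
  arena_wh <- c(layout$compartment_size_cm[1],
                2 * layout$compartment_size_cm[2])
  tracks <- list(path_to_track(paths[[1]], ids[1], fps, arena_wh),
                 path_to_track(paths[[2]], ids[2], fps, arena_wh))
  names(tracks) <- ids
  mp <- spec$mark_pct
  mark_pct <- c(mp[1] + spec$divergence * mp[2],
                mp[1] - spec$divergence * mp[2])
  names(mark_pct) <- c(ids[dom], ids[sub])
  list(tracks = tracks,
       events = ethogram_events(events),
       truth = list(dominant = ids[dom],
                    flights = stats::setNames(flights_s, ids),
                    hide_bouts = stats::setNames(hide_bouts, ids),
                    mark_pct = mark_pct),
       layout = layout)
}

# crop a track to a half-open time window (frame grid restarts at 0)
crop_track <- function(track, window) {
  fr <- window_frames(window, track$frame_rate_hz, n_frames(track))
  pose_track(track$mouse_id, track$frame_rate_hz,
             track$x[fr, , drop = FALSE], track$y[fr, , drop = FALSE],
             track$confidence[fr, , drop = FALSE])
}

# behavior-matrix row for one mouse and phase from its events + track
phase_row <- function(mouse_id, pair_id, events, track, layout, own_comp,
                      window, phase_tag, min_s = 1) {
  sub <- crop_track(track, window)
  cl <- clean_track(sub)
  wlen <- diff(window)
  data.frame(
    mouse_id = mouse_id, pair_id = pair_id, strain = "synthetic",
    phase = phase_tag,
    attacks = behavior_counts(events, mouse_id, "attack", window),
    chases = behavior_counts(events, mouse_id, "chase", window),
    flights = behavior_counts(events, mouse_id, "flight", window),
    uprights = behavior_counts(events, mouse_id, "upright", window),
    locomotion_cm = locomotion(cl),
    exploration_frac = exploration_time(cl, layout, own_comp) / wlen,
    hiding_frac = hiding_time(cl, layout) / wlen,
    stringsAsFactors = FALSE)
}

#' Simulate a whole cohort
#'
#' Generates `n_pairs` independent pairs under per-pair seeds derived from
#' the cohort seed by a fixed counter scheme (`seed * 10000 + pair index`),
#' and assembles the late-phase behavior matrix by running the package's own
#' metric functions on the generated tracks and events.
#'
#' @param spec A [cohort_spec()].
#' @param compute_metrics Assemble the behavior matrix (default `TRUE`)?
#' @param keep_tracks Keep the pose tracks of every pair in the result
#'   (default `FALSE`; they are large)?
#' @param out_dir Optional directory: writes each pair's pose CSV and event
#'   CSV, the layout YAML and the behavior matrix CSV.
#' @return A list with `spec`, `pair_table` (`mouse_id`, `pair_id`),
#'   `events` (all pairs), `truth` (per pair), `behavior_matrix` (late
#'   phase; `NULL` unless computed) and optionally `pairs` (full per-pair
#'   bundles when `keep_tracks`).
#' @export
simulate_cohort <- function(spec, compute_metrics = TRUE,
                            keep_tracks = FALSE, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  layout <- default_layout(frame_rate_hz = spec$frame_rate_hz)
  phases <- phase_windows(spec$session_min)
  rows <- list(); truth <- list(); events_all <- list(); bundles <- list()
  pair_table <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_layout(layout, file.path(out_dir, "layout.yml"))
  }
  for (i in seq_len(spec$n_pairs)) {
    pid <- sprintf("pair%02d", i)
    pr <- simulate_pair(spec, pair_seed = spec$seed * 10000 + i,
                        pair_id = pid, layout = layout)
    ids <- names(pr$tracks)
    pair_table[[i]] <- data.frame(mouse_id = ids, pair_id = pid,
                                  stringsAsFactors = FALSE)
    truth[[pid]] <- pr$truth
    events_all[[i]] <- as.data.frame(pr$events)
    if (compute_metrics) {
      for (k in 1:2)
        rows[[length(rows) + 1L]] <-
          phase_row(ids[k], pid, pr$events, pr$tracks[[k]], layout, k,
                    phases$late, "late")
    }
    if (!is.null(out_dir)) {
      write_pose_table(pr$tracks, file.path(out_dir, paste0(pid, "_poses.csv")))
      write_events(pr$events, file.path(out_dir, paste0(pid, "_events.csv")))
    }
    if (keep_tracks) bundles[[pid]] <- pr
  }
  bm <- if (compute_metrics) behavior_matrix(do.call(rbind, rows)) else NULL
  if (!is.null(out_dir) && !is.null(bm))
    write_behavior_matrix(bm, file.path(out_dir, "behavior_matrix.csv"))
  out <- list(spec = spec,
              pair_table = do.call(rbind, pair_table),
              events = ethogram_events(do.call(rbind, events_all)),
              truth = truth, behavior_matrix = bm)
  if (keep_tracks) out$pairs <- bundles
  out
}

# rasterize one tilted elliptical patch; returns linear indices
ellipse_px <- function(nr, nc, cx, cy, a, b, theta) {
  x0 <- max(1L, floor(cx - a)); x1 <- min(nc, ceiling(cx + a))
  y0 <- max(1L, floor(cy - a)); y1 <- min(nr, ceiling(cy + a))
  if (x0 > x1 || y0 > y1) return(integer(0))
  gx <- x0:x1; gy <- y0:y1
  xx <- rep(gx, each = length(gy)) - cx
  yy <- rep(gy, times = length(gx)) - cy
  u <- xx * cos(theta) + yy * sin(theta)
  v <- -xx * sin(theta) + yy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  # 1-based linear index into an nr x nc matrix (column-major)
  (rep(gx, each = length(gy))[inside] - 1L) * nr +
    rep(gy, times = length(gx))[inside]
}

#' Render a synthetic floor image with known mark areas
#'
#' Draws yellow (fluorescein) and fuchsia (erythrosin) streak/spot patches on
#' a near-white floor raster until each dye's target percent of the arena is
#' reached, then adds a mild illumination gradient and pixel noise. The
#' returned truth raster records the exact drawn label of every pixel, so
#' segmentation accuracy can be scored against ground truth.
#'
#' @param mark_pct Named or ordered length-2 numeric: target percent of arena
#'   area for fluorescein and erythrosin.
#' @param px_per_cm Raster scale (default 2).
#' @param arena_cm Arena size `c(width, height)` in cm (default 120 x 120).
#' @param noise_sd Gaussian pixel noise SD (default 0.01).
#' @param seed Optional seed.
#' @return A list with `image` (a [floor_image()]) and `truth` (integer
#'   matrix: 0 background, 1 fluorescein, 2 erythrosin).
#' @export
render_mark_image <- function(mark_pct, px_per_cm = 2,
                              arena_cm = c(120, 120), noise_sd = 0.01,
                              seed = NULL) {
  stopifnot(length(mark_pct) == 2L, all(mark_pct >= 0))
  if (!is.null(seed)) set.seed(seed)
  nr <- as.integer(arena_cm[2] * px_per_cm)
  nc <- as.integer(arena_cm[1] * px_per_cm)
  truth <- matrix(0L, nr, nc)
  targets <- round(mark_pct / 100 * nr * nc)
  for (d in 1:2) {
    guard <- 0L
    while (sum(truth == d) < targets[d] && guard < 10000L) {
      guard <- guard + 1L
      streak <- stats::runif(1) < 0.6
      a <- stats::runif(1, if (streak) 2 else 0.5, if (streak) 6 else 1.5) *
        px_per_cm
      b <- stats::runif(1, 0.25, 0.6) * px_per_cm
      px <- ellipse_px(nr, nc, stats::runif(1, 1, nc), stats::runif(1, 1, nr),
                       a, b, stats::runif(1, 0, pi))
      px <- px[truth[px] == 0L]  # never overwrite the other dye
      need <- targets[d] - sum(truth == d)
      if (length(px) > need) px <- px[seq_len(need)]
      truth[px] <- d
    }
  }
  base <- c(0.93, 0.92, 0.90)
  cols <- rbind(fluorescein = c(0.80, 0.88, 0.25),
                erythrosin = c(0.93, 0.35, 0.60))
  img <- array(0, c(nr, nc, 3))
  for (ch in 1:3) {
    m <- matrix(base[ch], nr, nc)
    for (d in 1:2) m[truth == d] <- cols[d, ch]
    # illumination gradient across x plus pixel noise
    grad <- matrix(rep(seq(0.92, 1, length.out = nc), each = nr), nr, nc)
    img[, , ch] <- pmin(1, pmax(0, m * grad +
                                  stats::rnorm(nr * nc, 0, noise_sd)))
  }
  list(image = floor_image(img, px_per_cm), truth = truth)
}
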