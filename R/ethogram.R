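#' Scored behavior events
#'
#' Fighting behaviors are scored manually as timed bouts with a fixed
#' vocabulary: attack (lunges leading to physical contact), chase (rapid
#' pursuit without contact), flight (sudden acceleration away from the
#' opponent) and upright (defensive posture on the hind paws). Each event
#' carries the acting mouse and onset/offset in seconds from session start.
#'
#' @name ethogram
NULL

BEHAVIORS <- c("attack", "chase", "flight", "upright")

#' Validate an ethogram event table
#'
#' @param events A data frame with columns `mouse_id`, `behavior`, `onset_s`,
#'   `offset_s` (other columns, e.g. `pair_id`, pass through).
#' @return The validated data frame (class `ethogram_events` prepended).
#' @export
ethogram_events <- function(events) {
  events <- as.data.frame(events)
  need <- c("mouse_id", "behavior", "onset_s", "offset_s")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("event table is missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(events$behavior), BEHAVIORS)
  if (length(bad))
    stop("unknown behaviors: ", paste(bad, collapse = ", "),
         " (vocabulary: ", paste(BEHAVIORS, collapse = ", "), ")")
  if (any(events$offset_s < events$onset_s))
    stop("event offsets must not precede onsets")
  class(events) <- unique(c("ethogram_events", class(events)))
  events
}

#' Read / write ethogram event tables as CSV
#'
#' Plain CSV with columns `mouse_id`, `behavior`, `onset_s`, `offset_s` (and
#' optionally `pair_id`), the export format of manual annotation tools.
#'
#' @param path CSV path.
#' @param events An event table.
#' @return `read_events()` a validated event table; `write_events()` `path`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event table not found: ", path)
  ethogram_events(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Phase windows of the territorial challenge
#'
#' Behaviors are analyzed in an early phase (first 20 min after the gate
#' opens) and a late phase. The default late phase is the last 20 min of the
#' session; `late = "100_110"` selects the 100-110 min variant used for some
#' published difference scores. Both are supported because the source
#' descriptions differ; neither is asserted as canonical.
#'
#' @param session_min Session length in minutes (default 120).
#' @param late `"last20"` (default) or `"100_110"`.
#' @param subinterval_min Width of analysis subintervals in minutes (default 10).
#' @return A list with `early` and `late` windows (seconds, half-open) and
#'   `subinterval_s`.
#' @export
phase_windows <- function(session_min = 120, late = c("last20", "100_110"),
                          subinterval_min = 10) {
  late <- match.arg(late)
  s <- session_min * 60
  lw <- if (late == "last20") c(s - 1200, s) else c(6000, 6600)
  if (lw[1] < 1200)
    stop("late window overlaps the early window for this session length")
  list(early = c(0, 1200), late = lw, subinterval_s = subinterval_min * 60)
}

#' Count behavior events in a window
#'
#' Events are assigned to windows by onset time (half-open `[start, end)`);
#' an event straddling a window boundary counts once, in its onset window.
#'
#' @param events An event table.
#' @param mouse_id Acting mouse.
#' @param behavior One of `"attack"`, `"chase"`, `"flight"`, `"upright"`.
#' @param window `c(start_s, end_s)`.
#' @return Integer count.
#' @export
behavior_counts <- function(events, mouse_id, behavior, window) {
  if (!behavior %in% BEHAVIORS)
    stop("unknown behavior '", behavior, "'")
  stopifnot(length(window) == 2L, window[2] > window[1])
  sum(events$mouse_id == mouse_id & events$behavior == behavior &
      events$onset_s >= window[1] & events$onset_s < window[2])
}

#' Within-pair difference of a behavior value
#'
#' @param matrix A behavior matrix (see [behavior_matrix()]): one row per
#'   mouse with `mouse_id`, `pair_id` and behavior columns.
#' @param pair Pair identifier.
#' @param behavior Behavior column name.
#' @param absolute Return `|difference|`? (default `FALSE`; the signed value
#'   is first-listed minus second-listed mouse and is antisymmetric in the
#'   pair order).
#' @return Numeric difference.
#' @export
pair_difference <- function(matrix, pair, behavior, absolute = FALSE) {
  rows <- matrix[matrix$pair_id == pair, , drop = FALSE]
  if (nrow(rows) != 2L)
    stop("pair '", pair, "' does not have exactly 2 members in the matrix")
  if (!behavior %in% names(rows))
    stop("behavior column '", behavior, "' not in matrix")
  d <- rows[[behavior]][1] - rows[[behavior]][2]
  if (absolute) abs(d) else d
}

#' Dominant-minus-subordinate differences across subintervals
#'
#' For each behavior and each subinterval, the difference between the pair's
#' dominant and subordinate (as labeled by [assign_ranks()]); this is the
#' quantity whose growth over the session traces the emergence of the
#' hierarchy.
#'
#' @param values Long data frame with columns `mouse_id`, `pair_id`,
#'   `subinterval`, `behavior`, `value` (e.g. per-subinterval counts from
#'   [behavior_counts()] or occupancy fractions).
#' @param ranks Rank table from [assign_ranks()] (columns `pair_id`,
#'   `dominant`, `subordinate`).
#' @return Data frame `pair_id`, `behavior`, `subinterval`,
#'   `diff` (dominant minus subordinate).
#' @export
difference_evolution <- function(values, ranks) {
  need <- c("mouse_id", "pair_id", "subinterval", "behavior", "value")
  miss <- setdiff(need, names(values))
  if (length(miss))
    stop("values table is missing columns: ", paste(miss, collapse = ", "))
  unlabeled <- setdiff(unique(values$pair_id), ranks$pair_id)
  if (length(unlabeled))
    stop("no dominance labels for pair(s): ",
         paste(unlabeled, collapse = ", "))
  out <- list()
  for (p in unique(values$pair_id)) {
    r <- ranks[ranks$pair_id == p, ]
    vp <- values[values$pair_id == p, ]
    for (b in unique(vp$behavior)) {
      vb <- vp[vp$behavior == b, ]
      for (s in unique(vb$subinterval)) {
        vs <- vb[vb$subinterval == s, ]
        vd <- vs$value[vs$mouse_id == r$dominant]
        vsub <- vs$value[vs$mouse_id == r$subordinate]
        if (length(vd) != 1L || length(vsub) != 1L)
          stop("pair '", p, "', behavior '", b, "', subinterval '", s,
               "': need exactly one value per pair member")
        out[[length(out) + 1L]] <- data.frame(
          pair_id = p, behavior = b, subinterval = s, diff = vd - vsub,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Flight-aligned speed and distance kinematics
#'
#' Implements the peri-flight averaging procedure: for every flight event,
#' the speed trace is restricted to an asymmetric search window around the
#' flight onset (`pre_s` before to `post_s` after), the frame of steepest
#' positive slope of the smoothed speed (the moment of maximum acceleration)
#' is located, and a symmetric window of `window_s` seconds is centered
#' there. Speed and distance windows from the same centers, pooled over all
#' flights of all mice, are then averaged frame by frame.
#'
#' Slope is a centered finite difference of the smoothed speed; ties are
#' broken to the earliest frame. Windows partially outside the recording
#' contribute their available frames to the missing-aware mean; flights whose
#' search window is entirely outside the recording (or has no defined slope)
#' are skipped and reported.
#'
#' @param flights Event table rows of flights: columns `mouse_id`, `onset_s`
#'   (a full [ethogram_events()] table may be passed; only `behavior ==
#'   "flight"` rows are used when a `behavior` column is present).
#' @param speed Named list (by `mouse_id`) of per-frame speed series sharing
#'   one frame grid (cm/s).
#' @param distance Per-frame inter-animal distance series on the same grid (cm).
#' @param frame_rate_hz Frame rate of the series.
#' @param pre_s,post_s Search window before/after flight onset (default 30/60 s).
#' @param window_s Width of the symmetric averaging window (default 8 s).
#' @param smooth_s Smoothing span applied to the speed before slope detection
#'   (default 0.5 s).
#' @return An object of class `flight_kinematics`: list with `time_s` (window
#'   offsets), `speed_mean`, `speed_sem`, `dist_mean`, `dist_sem`, `n`
#'   (contributing flights per frame), `centers` (per-flight detected center
#'   frames, 1-based) and `skipped` (row indices of skipped flights).
#' @export
flight_aligned_kinematics <- function(flights, speed, distance, frame_rate_hz,
                                      pre_s = 30, post_s = 60, window_s = 8,
                                      smooth_s = 0.5) {
  stopifnot(pre_s > 0, post_s > 0, window_s > 0, frame_rate_hz > 0)
  if ("behavior" %in% names(flights))
    flights <- flights[flights$behavior == "flight", , drop = FALSE]
  if (!all(c("mouse_id", "onset_s") %in% names(flights)))
    stop("flights need columns 'mouse_id' and 'onset_s'")
  fps <- frame_rate_hz
  nfr <- length(distance)
  sw <- as.integer(round(smooth_s * fps))
  if (sw %% 2L == 0L) sw <- sw + 1L
  smoothed <- lapply(speed, moving_average, w = sw)
  half <- as.integer(round(window_s / 2 * fps))
  offsets <- seq.int(-half, half)
  speed_w <- matrix(NA_real_, nrow(flights), length(offsets))
  dist_w <- speed_w
  centers <- rep(NA_integer_, nrow(flights))
  skipped <- integer(0)
  for (i in seq_len(nrow(flights))) {
    m <- as.character(flights$mouse_id[i])
    if (!m %in% names(speed))
      stop("no speed series for mouse '", m, "'")
    v <- smoothed[[m]]
    f0 <- as.integer(round(flights$onset_s[i] * fps)) + 1L
    lo <- max(1L, f0 - as.integer(round(pre_s * fps)))
    hi <- min(nfr, f0 + as.integer(round(post_s * fps)))
    if (lo > nfr || hi < 1L || lo >= hi) {
      skipped <- c(skipped, i)
      next
    }
    seg <- v[lo:hi]
    ns <- length(seg)
    slope <- rep(NA_real_, ns)
    if (ns >= 3L)
      slope[2:(ns - 1L)] <- (seg[3:ns] - seg[1:(ns - 2L)]) / 2
    if (!any(is.finite(slope))) {
      skipped <- c(skipped, i)
      next
    }
    slope[!is.finite(slope)] <- -Inf
    ctr <- lo + which.max(slope) - 1L
    centers[i] <- ctr
    idx <- ctr + offsets
    ok <- idx >= 1L & idx <= nfr
    speed_w[i, ok] <- speed[[m]][idx[ok]]
    dist_w[i, ok] <- distance[idx[ok]]
  }
  col_stats <- function(w) {
    n <- colSums(is.finite(w))
    mu <- suppressWarnings(apply(w, 2, function(col)
      mean(col[is.finite(col)])))
    sdv <- suppressWarnings(apply(w, 2, function(col)
      stats::sd(col[is.finite(col)])))
    sem <- ifelse(n > 1, sdv / sqrt(n), ifelse(n == 1, 0, NA_real_))
    # a single contributing flight has no dispersion: SEM 0 by convention
    sem[n >= 1 & !is.finite(sem)] <- 0
    list(mean = mu, sem = sem, n = n)
  }
  sp <- col_stats(speed_w)
  di <- col_stats(dist_w)
  structure(list(time_s = offsets / fps,
                 speed_mean = sp$mean, speed_sem = sp$sem,
                 dist_mean = di$mean, dist_sem = di$sem, n = sp$n,
                 centers = data.frame(mouse_id = flights$mouse_id,
                                      onset_s = flights$onset_s,
                                      center_frame = centers),
                 skipped = skipped),
            class = "flight_kinematics")
}

#' @export
print.flight_kinematics <- function(x, ...) {
  cat(sprintf(paste0("<flight_kinematics> %d flights (%d skipped), ",
                     "window %.1f..%.1f s, peak mean speed %.1f cm/s\n"),
              nrow(x$centers), length(x$skipped),
              min(x$time_s), max(x$time_s),
              suppressWarnings(max(x$speed_mean, na.rm = TRUE))))
  invisible(x)
}

#' Write kinematics traces as CSV
#'
#' One row per window frame: time offset, mean and SEM of speed and distance,
#' and the number of contributing flights.
#'
#' @param kin A `flight_kinematics` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kinematics <- function(kin, path) {
  stopifnot(inherits(kin, "flight_kinematics"))
  utils::write.csv(data.frame(time_s = kin$time_s,
                              speed_mean = kin$speed_mean,
                              speed_sem = kin$speed_sem,
                              dist_mean = kin$dist_mean,
                              dist_sem = kin$dist_sem,
                              n = kin$n),
                   path, row.names = FALSE)
  invisible(path)
}

#' Attack penetrance of a cohort
#'
#' Fraction of pairs in which at least one member showed at least one attack.
#'
#' @param events An event table (any columns beyond the standard ones pass
#'   through).
#' @param pairs Data frame mapping `mouse_id` to `pair_id`, one row per mouse.
#' @return Fraction in `[0, 1]`.
#' @export
attack_penetrance <- function(events, pairs) {
  stopifnot(all(c("mouse_id", "pair_id") %in% names(pairs)),
            nrow(pairs) >= 2L)
  attackers <- unique(events$mouse_id[events$behavior == "attack"])
  hit <- unique(pairs$pair_id[pairs$mouse_id %in% attackers])
  length(hit) / length(unique(pairs$pair_id))
}
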