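#' Dwell-bout extraction and occupancy metrics
#'
#' Occupancy of an ROI is handled as maximal runs of consecutive frames
#' ("bouts") on half-open, 0-based frame intervals; durations are computed in
#' frames and converted to seconds only at the end, so no float accumulation
#' occurs. Sub-second bouts (`< 1` s by default) are discarded per ROI before
#' any summation, mirroring the artifact-rejection step applied to raw
#' tracking quantifications.
#'
#' @name dwell
NULL

#' Extract dwell bouts for one ROI
#'
#' @param labels An [roi_labels()] object.
#' @param roi_name Name of the ROI to scan. Frames with missing anchor
#'   coordinates count as outside.
#' @return A data frame with columns `roi_name`, `start_frame`, `end_frame`
#'   (half-open, 0-based) and `duration_s`, with the frame rate attached as
#'   attribute `"frame_rate_hz"`.
#' @export
dwell_bouts <- function(labels, roi_name) {
  stopifnot(inherits(labels, "roi_labels"))
  if (!roi_name %in% colnames(labels$membership))
    stop("unknown ROI '", roi_name, "'")
  inside <- labels$membership[, roi_name]
  inside[is.na(inside)] <- FALSE
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  out <- data.frame(roi_name = rep(roi_name, sum(keep)),
                    start_frame = starts[keep],
                    end_frame = ends[keep],
                    stringsAsFactors = FALSE)
  out$duration_s <- (out$end_frame - out$start_frame) / labels$frame_rate_hz
  attr(out, "frame_rate_hz") <- labels$frame_rate_hz
  out
}

#' Discard sub-threshold dwell bouts
#'
#' Retains bouts with `duration_s >= min_s`; strictly shorter bouts are
#' discarded, so a bout of exactly `min_s` (45 frames at 45 fps for the
#' default 1 s) is kept. Comparison is done in whole frames when the frame
#' rate is known, avoiding float round-off.
#'
#' @param bouts A bout data frame from [dwell_bouts()].
#' @param min_s Minimum retained duration in seconds (default 1).
#' @return The filtered bout data frame (attributes preserved).
#' @export
min_dwell_filter <- function(bouts, min_s = 1.0) {
  stopifnot(min_s >= 0)
  fps <- attr(bouts, "frame_rate_hz")
  keep <- if (!is.null(fps)) {
    min_frames <- as.integer(ceiling(min_s * fps - 1e-9))
    (bouts$end_frame - bouts$start_frame) >= min_frames
  } else {
    bouts$duration_s >= min_s - 1e-12
  }
  out <- bouts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "frame_rate_hz") <- fps
  out
}

# logical per-frame vector of membership in any of `roi_names`,
# after per-ROI bout filtering
filtered_occupancy <- function(labels, roi_names, min_s) {
  n <- nrow(labels$membership)
  occ <- logical(n)
  for (nm in roi_names) {
    b <- min_dwell_filter(dwell_bouts(labels, nm), min_s)
    for (k in seq_len(nrow(b)))
      occ[(b$start_frame[k] + 1L):b$end_frame[k]] <- TRUE
  }
  occ
}

as_labels <- function(x, layout, anchor) {
  if (inherits(x, "roi_labels")) x else roi_labels(x, layout, anchor)
}

#' Hiding time
#'
#' Seconds spent in the union of the 12 hiding ROIs (8 compartment corners,
#' 2 cage tops, 2 food-column tops), after the per-ROI sub-second bout filter.
#' Frames inside several hiding ROIs at once (the food top lies within the
#' cage footprint) are counted once.
#'
#' @param track A [pose_track()] or precomputed [roi_labels()]; or a list of
#'   tracks, in which case a named vector is returned.
#' @param layout An [arena_layout()].
#' @param window Optional `c(start_s, end_s)` half-open window.
#' @param min_s Bout filter threshold, seconds (default 1).
#' @param anchor Body part defining the animal's position.
#' @return Seconds (scalar, or named vector for a list of tracks).
#' @export
hiding_time <- function(track, layout, window = NULL, min_s = 1.0,
                        anchor = "middle_back") {
  if (is.list(track) && !inherits(track, c("pose_track", "roi_labels")))
    return(vapply(track, hiding_time, 0, layout = layout, window = window,
                  min_s = min_s, anchor = anchor))
  lab <- as_labels(track, layout, anchor)
  occ <- filtered_occupancy(lab, hiding_rois(layout), min_s)
  fr <- window_frames(window, lab$frame_rate_hz, length(occ))
  sum(occ[fr]) / lab$frame_rate_hz
}

#' Exploration time
#'
#' Time spent in the opponent's compartment minus the time spent in that
#' compartment's hiding zones (all after the sub-second bout filter); by
#' construction never negative.
#'
#' @param track A [pose_track()] or [roi_labels()].
#' @param layout An [arena_layout()].
#' @param own_compartment_id Compartment (1 or 2) the mouse was habituated in.
#' @inheritParams hiding_time
#' @return Seconds.
#' @export
exploration_time <- function(track, layout, own_compartment_id,
                             window = NULL, min_s = 1.0,
                             anchor = "middle_back") {
  own_compartment_id <- as.integer(own_compartment_id)
  stopifnot(own_compartment_id %in% c(1L, 2L))
  opp <- 3L - own_compartment_id
  lab <- as_labels(track, layout, anchor)
  comp_names <- names(layout$rois)[vapply(layout$rois, function(r)
    r$category == "compartment", TRUE)]
  opp_comp <- comp_names[vapply(layout$rois[comp_names], function(r)
    r$compartment_id == opp, TRUE)]
  in_comp <- filtered_occupancy(lab, opp_comp, min_s)
  hide_opp <- hiding_rois(layout)
  hide_opp <- hide_opp[vapply(layout$rois[hide_opp], function(r)
    r$compartment_id == opp, TRUE)]
  in_hide <- filtered_occupancy(lab, hide_opp, min_s)
  fr <- window_frames(window, lab$frame_rate_hz, length(in_comp))
  sum(in_comp[fr] & !in_hide[fr]) / lab$frame_rate_hz
}

#' Proximity time
#'
#' Total time two mice spend closer than `threshold_cm` (anchor to anchor)
#' while occupying the same member of the proximity ROI set (each
#' compartment, each cage top, each food-column top), occupancy taken after
#' the sub-second bout filter. Frames where either anchor is missing are
#' excluded. Symmetric in the two tracks.
#'
#' @param track_a,track_b [pose_track()] objects on a shared frame grid.
#' @param layout An [arena_layout()].
#' @param threshold_cm Distance threshold, strict `<` (default 10).
#' @inheritParams hiding_time
#' @return Seconds.
#' @export
proximity_time <- function(track_a, track_b, layout, threshold_cm = 10,
                           window = NULL, min_s = 1.0,
                           anchor = "middle_back") {
  if (n_frames(track_a) != n_frames(track_b))
    stop("tracks have different lengths (",
         n_frames(track_a), " vs ", n_frames(track_b), " frames)")
  la <- roi_labels(track_a, layout, anchor)
  lb <- roi_labels(track_b, layout, anchor)
  same <- logical(n_frames(track_a))
  for (nm in proximity_rois(layout)) {
    oa <- filtered_occupancy_one(la, nm, min_s)
    ob <- filtered_occupancy_one(lb, nm, min_s)
    same <- same | (oa & ob)
  }
  d <- distance_series(track_a, track_b, anchor)
  close_by <- !is.na(d) & d < threshold_cm
  fr <- window_frames(window, la$frame_rate_hz, length(same))
  sum(same[fr] & close_by[fr]) / la$frame_rate_hz
}

filtered_occupancy_one <- function(labels, roi_name, min_s)
  filtered_occupancy(labels, roi_name, min_s)

#' Summary trajectory metrics for one mouse
#'
#' Computes the trajectory-derived entries of the behavior matrix in one call:
#' locomotion (cm), hiding time (s), exploration time (s), mean speed (cm/s,
#' over frames with a defined speed) and per-ROI filtered dwell seconds.
#'
#' @param track A cleaned [pose_track()].
#' @param layout An [arena_layout()].
#' @param own_compartment_id Compartment (1 or 2) the mouse started in.
#' @inheritParams hiding_time
#' @return A list with elements `mouse_id`, `locomotion_cm`, `hiding_s`,
#'   `exploration_s`, `mean_speed_cms` and `per_roi_dwell_s` (named vector).
#' @export
trajectory_metrics <- function(track, layout, own_compartment_id,
                               window = NULL, min_s = 1.0,
                               anchor = "middle_back") {
  stopifnot(inherits(track, "pose_track"))
  lab <- roi_labels(track, layout, anchor)
  fr <- window_frames(window, lab$frame_rate_hz, n_frames(track))
  v <- speed_series(track, anchor)[fr]
  dwell <- vapply(names(layout$rois), function(nm) {
    occ <- filtered_occupancy(lab, nm, min_s)
    sum(occ[fr]) / lab$frame_rate_hz
  }, 0)
  list(mouse_id = track$mouse_id,
       locomotion_cm = locomotion(track, anchor, window),
       hiding_s = hiding_time(lab, layout, window, min_s),
       exploration_s = exploration_time(lab, layout, own_compartment_id,
                                        window, min_s),
       mean_speed_cms = mean(v[is.finite(v)]),
       per_roi_dwell_s = dwell)
}
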