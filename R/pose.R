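#' Pose tracks
#'
#' A pose track holds the per-frame 2-D coordinates (plus tracking confidence)
#' of the 8 annotated body parts of one mouse, in cm, on a fixed frame grid.
#'
#' @name pose
NULL

BODYPARTS <- c("nose", "right_ear", "left_ear", "middle_back",
               "right_side", "left_side", "tail_base", "tail_end")

#' Construct a pose track
#'
#' @param mouse_id Identifier of the animal.
#' @param frame_rate_hz Frames per second (> 0).
#' @param x,y Numeric frames x body-parts matrices of coordinates in cm, with
#'   body-part column names. `NA` marks missing samples.
#' @param confidence Optional matrix of tracking confidence in `[0, 1]`,
#'   same shape; defaults to 1 everywhere.
#'
#' @return An object of class `pose_track`.
#' @export
pose_track <- function(mouse_id, frame_rate_hz, x, y, confidence = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  storage.mode(x) <- "double"; storage.mode(y) <- "double"
  if (!identical(dim(x), dim(y)))
    stop("x and y coordinate matrices must have identical dimensions")
  if (is.null(colnames(x)))
    stop("coordinate matrices need body-part column names")
  colnames(y) <- colnames(x)
  if (is.null(confidence)) {
    confidence <- matrix(1, nrow(x), ncol(x), dimnames = dimnames(x))
  } else {
    confidence <- as.matrix(confidence)
    storage.mode(confidence) <- "double"
    if (!identical(dim(confidence), dim(x)))
      stop("confidence matrix must match coordinate dimensions")
    cf <- confidence[is.finite(confidence)]
    if (length(cf) && (min(cf) < 0 || max(cf) > 1))
      stop("confidence values must lie in [0, 1]")
    dimnames(confidence) <- dimnames(x)
  }
  stopifnot(frame_rate_hz > 0)
  structure(
    list(mouse_id = as.character(mouse_id),
         frame_rate_hz = as.numeric(frame_rate_hz),
         bodyparts = colnames(x), x = x, y = y, confidence = confidence),
    class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> mouse '%s': %d frames @ %g fps, %d body parts\n",
              x$mouse_id, nrow(x$x), x$frame_rate_hz, length(x$bodyparts)))
  invisible(x)
}

n_frames <- function(track) nrow(track$x)

#' Read a multi-animal tracking table
#'
#' Parses the CSV dialect exported by markerless pose-tracking software: a
#' multi-row header (scorer; optionally individuals; bodyparts; coords with
#' `x`/`y`/`likelihood` columns) above one row per frame. Column order in the
#' file does not matter; each declared (individual, body part) must provide
#' both an `x` and a `y` column, and `likelihood` defaults to 1 when absent.
#'
#' @param path CSV file path.
#' @param frame_rate_hz Frame rate to stamp on the tracks (default 45).
#' @param px_per_cm Optional pixels-per-cm scale; coordinates are divided by it
#'   (default 1, i.e. the file is already in cm).
#' @return A named list of [pose_track()], one per individual.
#' @export
read_pose_table <- function(path, frame_rate_hz = 45, px_per_cm = 1) {
  if (!file.exists(path)) stop("pose table not found: ", path)
  stopifnot(px_per_cm > 0)
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  if (nrow(raw) < 4L) stop("malformed pose table: too few rows")
  tags <- raw[[1]][1:4]
  has_indiv <- identical(tags[2], "individuals")
  bp_row <- if (has_indiv) 3L else 2L
  coord_row <- bp_row + 1L
  if (!identical(tags[bp_row], "bodyparts") ||
      !identical(tags[coord_row], "coords"))
    stop("malformed pose table header: expected 'bodyparts' and 'coords' rows")
  idx <- seq(2L, ncol(raw))
  indiv <- if (has_indiv) as.character(unlist(raw[2L, idx])) else
    rep("animal1", length(idx))
  bps <- as.character(unlist(raw[bp_row, idx]))
  coords <- as.character(unlist(raw[coord_row, idx]))
  bad <- !coords %in% c("x", "y", "likelihood")
  if (any(bad))
    stop("malformed pose table: unknown coords entries: ",
         paste(unique(coords[bad]), collapse = ", "))
  body <- raw[-seq_len(coord_row), , drop = FALSE]
  num <- suppressWarnings(
    vapply(body[idx], as.numeric, numeric(nrow(body))))
  num <- matrix(num, nrow = nrow(body))
  out <- list()
  for (an in unique(indiv)) {
    sel <- which(indiv == an)
    parts <- unique(bps[sel])
    nfr <- nrow(body)
    xm <- matrix(NA_real_, nfr, length(parts), dimnames = list(NULL, parts))
    ym <- xm; cm <- xm
    for (p in parts) {
      for (cc in c("x", "y")) {
        j <- sel[bps[sel] == p & coords[sel] == cc]
        if (length(j) != 1L)
          stop("pose table missing column '", cc, "' for body part '", p,
               "' of individual '", an, "'")
        if (cc == "x") xm[, p] <- num[, j] / px_per_cm
        else ym[, p] <- num[, j] / px_per_cm
      }
      j <- sel[bps[sel] == p & coords[sel] == "likelihood"]
      cm[, p] <- if (length(j) == 1L) num[, j] else 1
    }
    out[[an]] <- pose_track(an, frame_rate_hz, xm, ym, cm)
  }
  out
}

#' Write pose tracks in the multi-animal tracking-table dialect
#'
#' @param tracks A list of [pose_track()] sharing a frame grid.
#' @param path Output CSV path.
#' @param scorer Scorer tag for the first header row.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(tracks, path, scorer = "territr") {
  stopifnot(length(tracks) >= 1L,
            all(vapply(tracks, inherits, TRUE, "pose_track")))
  nfr <- unique(vapply(tracks, n_frames, 1L))
  if (length(nfr) != 1L) stop("tracks must share the frame grid")
  cols <- list(); hdr_ind <- c(); hdr_bp <- c(); hdr_co <- c()
  for (tr in tracks) {
    for (p in tr$bodyparts) {
      cols <- c(cols, list(tr$x[, p], tr$y[, p], tr$confidence[, p]))
      hdr_ind <- c(hdr_ind, rep(tr$mouse_id, 3L))
      hdr_bp <- c(hdr_bp, rep(p, 3L))
      hdr_co <- c(hdr_co, c("x", "y", "likelihood"))
    }
  }
  m <- do.call(cbind, cols)
  lines <- c(
    paste(c("scorer", rep(scorer, ncol(m))), collapse = ","),
    paste(c("individuals", hdr_ind), collapse = ","),
    paste(c("bodyparts", hdr_bp), collapse = ","),
    paste(c("coords", hdr_co), collapse = ","))
  body <- cbind(seq_len(nfr) - 1L,
                matrix(format(m, digits = 10, trim = TRUE, scientific = FALSE),
                       nrow = nfr))
  body[body == "NA"] <- ""
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  utils::write.table(body, con, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

# centered moving sum with partial windows at the edges; w odd
run_sum <- function(v, w) {
  n <- length(v)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(0L, seq_len(n) - 1L - h)
  hi <- pmin(n, seq_len(n) + h)
  cs[hi + 1L] - cs[lo + 1L]
}

# NA-aware centered moving average (partial windows at edges);
# positions missing on input stay missing
moving_average <- function(v, w) {
  if (w <= 1L) return(v)
  ok <- is.finite(v)
  z <- ifelse(ok, v, 0)
  s <- run_sum(z, w)
  k <- run_sum(as.numeric(ok), w)
  out <- ifelse(k > 0, s / k, NA_real_)
  out[!ok] <- NA_real_
  out
}

# linear interpolation of interior NA runs no longer than max_gap frames
fill_short_gaps <- function(v, max_gap) {
  if (!anyNA(v)) return(v)
  ok <- which(is.finite(v))
  if (length(ok) < 2L) return(v)
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  filled <- stats::approx(ok, v[ok], xout = seq_along(v), rule = 1)$y
  out <- v
  for (i in which(r$values)) {
    if (r$lengths[i] <= max_gap && starts[i] > 1L && ends[i] < length(v))
      out[starts[i]:ends[i]] <- filled[starts[i]:ends[i]]
  }
  out
}

#' Clean a pose track
#'
#' Standard pre-processing of raw tracking output: samples below the
#' confidence threshold are set missing, missing runs no longer than
#' `max_gap_s` are linearly interpolated (longer runs, and leading/trailing
#' runs, stay missing), and coordinates are smoothed by a centered moving
#' average. Output length equals input length. None of the cleaning
#' parameters are published for the original assay; the defaults (threshold
#' 0.6, gap 0.5 s, 5-frame window at 45 fps) are package conventions.
#'
#' @param track A [pose_track()].
#' @param max_gap_s Longest missing run to interpolate, seconds (>= 0).
#' @param smooth_window_s Width of the smoothing window in seconds; rounded to
#'   the nearest odd frame count. `NULL` (default) means 5 frames.
#' @param conf_threshold Samples with confidence strictly below this are
#'   treated as missing.
#' @return A cleaned [pose_track()] with attribute `"all_missing"` flagging
#'   body parts that had no usable samples.
#' @export
clean_track <- function(track, max_gap_s = 0.5, smooth_window_s = NULL,
                        conf_threshold = 0.6) {
  stopifnot(inherits(track, "pose_track"), max_gap_s >= 0)
  fps <- track$frame_rate_hz
  w <- if (is.null(smooth_window_s)) 5L else {
    stopifnot(smooth_window_s >= 0)
    max(1L, as.integer(round(smooth_window_s * fps)))
  }
  if (w %% 2L == 0L) w <- w + 1L
  max_gap <- as.integer(floor(max_gap_s * fps + 1e-9))
  x <- track$x; y <- track$y
  low <- track$confidence < conf_threshold
  low[is.na(low)] <- TRUE
  x[low] <- NA_real_; y[low] <- NA_real_
  all_missing <- character(0)
  for (p in track$bodyparts) {
    if (!any(is.finite(x[, p]) & is.finite(y[, p]))) {
      all_missing <- c(all_missing, p)
      next
    }
    miss <- !is.finite(x[, p]) | !is.finite(y[, p])
    x[miss, p] <- NA_real_; y[miss, p] <- NA_real_
    x[, p] <- moving_average(fill_short_gaps(x[, p], max_gap), w)
    y[, p] <- moving_average(fill_short_gaps(y[, p], max_gap), w)
  }
  out <- pose_track(track$mouse_id, fps, x, y, track$confidence)
  attr(out, "all_missing") <- all_missing
  out
}

#' Instantaneous speed of a body part
#'
#' Centered finite difference of the anchor position scaled by the frame
#' rate: `speed[i] = |p[i+1] - p[i-1]| / 2 * fps` (cm/s). Missing wherever
#' either neighbor frame is missing; the first and last frames are always
#' missing.
#'
#' @param track A (cleaned) [pose_track()].
#' @param anchor Body-part name (default `"middle_back"`).
#' @return Numeric vector, one speed per frame, cm/s.
#' @export
speed_series <- function(track, anchor = "middle_back") {
  stopifnot(inherits(track, "pose_track"))
  if (!anchor %in% track$bodyparts)
    stop("unknown anchor body part '", anchor, "'")
  x <- track$x[, anchor]; y <- track$y[, anchor]
  n <- length(x)
  v <- rep(NA_real_, n)
  if (n >= 3L) {
    i <- 2:(n - 1L)
    dx <- x[i + 1L] - x[i - 1L]
    dy <- y[i + 1L] - y[i - 1L]
    v[i] <- sqrt(dx^2 + dy^2) / 2 * track$frame_rate_hz
  }
  v
}

#' Inter-animal distance series
#'
#' Euclidean distance between the anchor body parts of two mice sharing a
#' frame grid, cm; `NA` where either anchor is missing.
#'
#' @param track_a,track_b [pose_track()] objects on the same frame grid.
#' @param anchor Body-part name measured on both mice.
#' @return Numeric vector, one distance per frame.
#' @export
distance_series <- function(track_a, track_b, anchor = "middle_back") {
  stopifnot(inherits(track_a, "pose_track"), inherits(track_b, "pose_track"))
  if (n_frames(track_a) != n_frames(track_b))
    stop("tracks have different lengths (",
         n_frames(track_a), " vs ", n_frames(track_b), " frames)")
  sqrt((track_a$x[, anchor] - track_b$x[, anchor])^2 +
       (track_a$y[, anchor] - track_b$y[, anchor])^2)
}

# window in seconds (c(start, end), half-open) -> 1-based frame indices
window_frames <- function(window, fps, n) {
  if (is.null(window)) return(seq_len(n))
  stopifnot(length(window) == 2L, window[2] > window[1])
  f0 <- as.integer(floor(window[1] * fps + 1e-9)) + 1L
  f1 <- as.integer(ceiling(window[2] * fps - 1e-9))
  seq.int(max(1L, f0), min(n, f1))
}

#' Path length travelled
#'
#' Sum of displacements of the anchor between consecutive frames where both
#' frames have coordinates; steps spanning a missing frame are skipped, not
#' bridged.
#'
#' @param track A (cleaned) [pose_track()].
#' @param anchor Body-part name.
#' @param window Optional `c(start_s, end_s)` half-open time window; `NULL`
#'   uses the whole track.
#' @return Distance in cm.
#' @export
locomotion <- function(track, anchor = "middle_back", window = NULL) {
  stopifnot(inherits(track, "pose_track"))
  fr <- window_frames(window, track$frame_rate_hz, n_frames(track))
  if (length(fr) < 2L) return(0)
  x <- track$x[fr, anchor]; y <- track$y[fr, anchor]
  dx <- diff(x); dy <- diff(y)
  step <- sqrt(dx^2 + dy^2)
  sum(step[is.finite(step)])
}
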