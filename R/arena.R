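#' Regions of interest and the two-compartment arena
#'
#' The testing apparatus is a 120 x 120 cm open-top enclosure divided into two
#' 120 x 60 cm compartments that share their long wall, connected by a 4 cm
#' passage in the middle of the dividing wall. Each compartment holds a central
#' plexiglass home cage with a food column inside it, and its four 8 x 8 cm
#' floor corners are treated as refuge zones. All geometry lives in a single
#' fixed frame: origin at the arena's outer top-left corner, x rightward,
#' y downward, units cm (the coordinate convention of overhead video).
#'
#' @name arena
NULL

ROI_CATEGORIES <- c("compartment", "corner", "cage_top", "food_top",
                    "water_top", "passage", "custom")

#' Construct a region of interest
#'
#' @param name Short identifier, unique within a layout.
#' @param category One of `"compartment"`, `"corner"`, `"cage_top"`,
#'   `"food_top"`, `"water_top"`, `"passage"`, `"custom"`.
#' @param polygon Two-column numeric matrix of vertices (x, y) in cm, listed in
#'   order; the polygon is implicitly closed and must not self-intersect.
#' @param compartment_id Which compartment the ROI belongs to (1 or 2).
#'
#' @return An object of class `roi`.
#' @export
roi <- function(name, category, polygon, compartment_id) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  category <- match.arg(category, ROI_CATEGORIES)
  polygon <- as.matrix(polygon)
  storage.mode(polygon) <- "double"
  if (ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("polygon must be a matrix with >= 3 rows and 2 columns (x, y in cm)")
  if (any(!is.finite(polygon)))
    stop("polygon vertices must be finite")
  if (polygon_area(polygon) <= 0)
    stop("polygon of ROI '", name, "' has zero area (degenerate)")
  compartment_id <- as.integer(compartment_id)
  stopifnot(compartment_id %in% c(1L, 2L))
  dimnames(polygon) <- NULL
  structure(
    list(name = name, category = category, polygon = polygon,
         compartment_id = compartment_id),
    class = "roi")
}

# Shoelace area, sign-free.
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %s [%s, compartment %d] %d vertices, area %.1f cm^2\n",
              x$name, x$category, x$compartment_id, nrow(x$polygon),
              polygon_area(x$polygon)))
  invisible(x)
}

#' Construct an arena layout
#'
#' @param compartment_size_cm Numeric length-2: (width, height) of one
#'   compartment in cm.
#' @param wall_height_cm Wall height in cm (metadata only; the analysis is 2-D).
#' @param passage_width_cm Width of the passage through the dividing wall.
#' @param rois A list of [roi()] objects. Must contain exactly two
#'   `"compartment"` ROIs and exactly 12 hiding ROIs (categories `corner`,
#'   `cage_top`, `food_top`, `water_top`).
#' @param frame_rate_hz Video frame rate the pose tracks were acquired at.
#'
#' @return An object of class `arena_layout`.
#' @export
arena_layout <- function(compartment_size_cm, wall_height_cm, passage_width_cm,
                         rois, frame_rate_hz) {
  compartment_size_cm <- as.numeric(compartment_size_cm)
  stopifnot(length(compartment_size_cm) == 2L, all(compartment_size_cm > 0),
            wall_height_cm > 0, passage_width_cm > 0, frame_rate_hz > 0)
  stopifnot(is.list(rois), all(vapply(rois, inherits, TRUE, "roi")))
  names(rois) <- vapply(rois, `[[`, "", "name")
  if (anyDuplicated(names(rois)))
    stop("ROI names must be unique")
  n_comp <- sum(vapply(rois, function(r) r$category == "compartment", TRUE))
  if (n_comp != 2L)
    stop("layout must contain exactly 2 compartment ROIs, found ", n_comp)
  hide <- vapply(rois, function(r)
    r$category %in% c("corner", "cage_top", "food_top", "water_top"), TRUE)
  if (sum(hide) != 12L)
    stop("layout must designate exactly 12 hiding ROIs ",
         "(8 corners + 2 cage tops + 2 food tops), found ", sum(hide))
  # all vertices inside the arena bounding box (two stacked compartments)
  bbox <- c(compartment_size_cm[1], 2 * compartment_size_cm[2])
  for (r in rois) {
    p <- r$polygon
    if (any(p[, 1] < -1e-9 | p[, 1] > bbox[1] + 1e-9 |
            p[, 2] < -1e-9 | p[, 2] > bbox[2] + 1e-9))
      stop("ROI '", r$name, "' has vertices outside the arena bounding box")
  }
  structure(
    list(compartment_size_cm = compartment_size_cm,
         wall_height_cm = as.numeric(wall_height_cm),
         passage_width_cm = as.numeric(passage_width_cm),
         rois = rois,
         frame_rate_hz = as.numeric(frame_rate_hz)),
    class = "arena_layout")
}

#' @export
print.arena_layout <- function(x, ...) {
  cat(sprintf(paste0("<arena_layout> two %g x %g cm compartments, ",
                     "passage %g cm, %d ROIs (%d hiding), %g fps\n"),
              x$compartment_size_cm[1], x$compartment_size_cm[2],
              x$passage_width_cm, length(x$rois),
              length(hiding_rois(x)), x$frame_rate_hz))
  invisible(x)
}

#' The canonical two-compartment apparatus
#'
#' Builds the default arena: two 120 x 60 cm compartments stacked along y
#' (overall floor 120 x 120 cm), a 4 cm passage centered on the dividing wall,
#' a 25 x 25 cm central home-cage footprint per compartment with a 10
#' cm-diameter food-column disc at its center, and four 8 x 8 cm corner ROIs
#' per compartment. Twelve ROIs are designated hiding zones: the 8 corners,
#' the 2 cage tops (water-dispenser tops are part of the cage-top footprint)
#' and the 2 food-column tops.
#'
#' The 25 x 25 cm cage footprint and the exact corner placement are defaults,
#' not published dimensions; both are configurable through the arguments or by
#' editing a serialized layout.
#'
#' @param cage_size_cm Side of the square central-cage footprint (default 25).
#' @param food_diameter_cm Diameter of the food-column disc (default 10).
#' @param corner_size_cm Side of the square corner ROIs (default 8).
#' @param frame_rate_hz Acquisition frame rate (default 45).
#'
#' @return An [arena_layout()].
#' @examples
#' layout <- default_layout()
#' length(hiding_rois(layout))  # 12
#' @export
default_layout <- function(cage_size_cm = 25, food_diameter_cm = 10,
                           corner_size_cm = 8, frame_rate_hz = 45) {
  W <- 120; H <- 60  # one compartment, cm
  cs <- corner_size_cm
  rect <- function(x0, y0, x1, y1)
    cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  disc <- function(cx, cy, r, n = 32L) {
    th <- 2 * pi * (seq_len(n) - 1L) / n
    cbind(cx + r * cos(th), cy + r * sin(th))
  }
  rois <- list()
  for (comp in 1:2) {
    y0 <- (comp - 1L) * H
    pre <- paste0("c", comp, "_")
    rois[[length(rois) + 1L]] <-
      roi(paste0("compartment", comp), "compartment",
          rect(0, y0, W, y0 + H), comp)
    # four floor corners
    corner_boxes <- list(
      nw = rect(0, y0, cs, y0 + cs),
      ne = rect(W - cs, y0, W, y0 + cs),
      sw = rect(0, y0 + H - cs, cs, y0 + H),
      se = rect(W - cs, y0 + H - cs, W, y0 + H))
    for (nm in names(corner_boxes))
      rois[[length(rois) + 1L]] <-
        roi(paste0(pre, "corner_", nm), "corner", corner_boxes[[nm]], comp)
    cx <- W / 2; cy <- y0 + H / 2
    half <- cage_size_cm / 2
    rois[[length(rois) + 1L]] <-
      roi(paste0(pre, "cage_top"), "cage_top",
          rect(cx - half, cy - half, cx + half, cy + half), comp)
    rois[[length(rois) + 1L]] <-
      roi(paste0(pre, "food_top"), "food_top",
          disc(cx, cy, food_diameter_cm / 2), comp)
  }
  # passage: 4 cm opening centered on the dividing wall (y = 60), given a
  # 4 cm depth on either side so passage crossings are visible in 2-D
  pw <- 4
  rois[[length(rois) + 1L]] <-
    roi("passage", "passage", rect(W / 2 - pw / 2, H - pw / 2,
                                   W / 2 + pw / 2, H + pw / 2), 1L)
  arena_layout(compartment_size_cm = c(W, H), wall_height_cm = 70,
               passage_width_cm = pw, rois = rois,
               frame_rate_hz = frame_rate_hz)
}

#' Hiding / proximity ROI subsets
#'
#' `hiding_rois()` returns the names of the 12 refuge ROIs whose summed,
#' bout-filtered occupancy defines hiding time. `proximity_rois()` returns the
#' ROI set used for the same-ROI clause of proximity time: each compartment,
#' each cage top and each food-column top (central cage and cage top coincide
#' in the 2-D floor plan).
#'
#' @param layout An [arena_layout()].
#' @return Character vector of ROI names.
#' @export
hiding_rois <- function(layout) {
  stopifnot(inherits(layout, "arena_layout"))
  keep <- vapply(layout$rois, function(r)
    r$category %in% c("corner", "cage_top", "food_top", "water_top"), TRUE)
  names(layout$rois)[keep]
}

#' @rdname hiding_rois
#' @export
proximity_rois <- function(layout) {
  stopifnot(inherits(layout, "arena_layout"))
  keep <- vapply(layout$rois, function(r)
    r$category %in% c("compartment", "cage_top", "food_top"), TRUE)
  names(layout$rois)[keep]
}

#' Point-in-ROI query
#'
#' Boundary points count as inside (closed polygons), so membership is
#' deterministic for points lying exactly on an ROI edge or vertex.
#'
#' @param p Numeric length-2 point (x, y) in cm, or an n x 2 matrix of points.
#' @param roi An [roi()] object.
#' @return Logical, one value per point.
#' @export
point_in_roi <- function(p, roi) {
  stopifnot(inherits(roi, "roi"))
  p <- rbind(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 2L) stop("p must be (x, y) or an n x 2 matrix")
  if (any(!is.finite(p))) stop("coordinates must be finite")
  pg <- roi$polygon
  pracma::inpolygon(p[, 1], p[, 2], pg[, 1], pg[, 2], boundary = TRUE)
}

#' Per-frame ROI membership of a tracked body part
#'
#' Evaluates, for every frame of a pose track, which layout ROIs contain the
#' anchor body part. Frames where the anchor coordinates are missing are
#' flagged missing and carry `NA` membership.
#'
#' @param track A [pose_track()].
#' @param layout An [arena_layout()].
#' @param anchor Body-part name used as the animal's position
#'   (default `"middle_back"`).
#' @return An object of class `roi_labels`: a list with `membership` (logical
#'   frames x ROIs matrix), `missing` (logical per frame) and `frame_rate_hz`.
#' @export
roi_labels <- function(track, layout, anchor = "middle_back") {
  stopifnot(inherits(track, "pose_track"), inherits(layout, "arena_layout"))
  if (!anchor %in% track$bodyparts)
    stop("unknown anchor body part '", anchor, "'; track has: ",
         paste(track$bodyparts, collapse = ", "))
  x <- track$x[, anchor]; y <- track$y[, anchor]
  miss <- !is.finite(x) | !is.finite(y)
  n <- length(x)
  memb <- matrix(NA, n, length(layout$rois),
                 dimnames = list(NULL, names(layout$rois)))
  ok <- !miss
  if (any(ok)) {
    for (nm in names(layout$rois)) {
      pg <- layout$rois[[nm]]$polygon
      memb[ok, nm] <- pracma::inpolygon(x[ok], y[ok], pg[, 1], pg[, 2],
                                        boundary = TRUE)
    }
  }
  structure(list(membership = memb, missing = miss,
                 frame_rate_hz = track$frame_rate_hz),
            class = "roi_labels")
}

#' @export
print.roi_labels <- function(x, ...) {
  cat(sprintf("<roi_labels> %d frames x %d ROIs, %d missing frames\n",
              nrow(x$membership), ncol(x$membership), sum(x$missing)))
  invisible(x)
}

#' Read / write an arena layout as a YAML configuration
#'
#' The layout serializes to a structured text file (scalars plus per-ROI
#' vertex lists) and round-trips exactly: `read_layout(write_layout(l, f))`
#' reproduces `l` bit for bit.
#'
#' @param layout An [arena_layout()].
#' @param path File path of the YAML configuration.
#' @return `write_layout()` returns `path` invisibly; `read_layout()` an
#'   [arena_layout()].
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "arena_layout"))
  rois <- lapply(unname(layout$rois), function(r)
    list(name = r$name, category = r$category,
         compartment_id = r$compartment_id,
         x = as.numeric(r$polygon[, 1]), y = as.numeric(r$polygon[, 2])))
  doc <- list(compartment_size_cm = layout$compartment_size_cm,
              wall_height_cm = layout$wall_height_cm,
              passage_width_cm = layout$passage_width_cm,
              frame_rate_hz = layout$frame_rate_hz,
              rois = rois)
  writeLines(yaml::as.yaml(doc, precision = 17L), path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  doc <- yaml::read_yaml(path)
  need <- c("compartment_size_cm", "wall_height_cm", "passage_width_cm",
            "frame_rate_hz", "rois")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("layout file is missing required fields: ", paste(miss, collapse = ", "))
  rois <- lapply(doc$rois, function(r) {
    roi(r$name, r$category, cbind(as.numeric(r$x), as.numeric(r$y)),
        r$compartment_id)
  })
  arena_layout(as.numeric(doc$compartment_size_cm),
               as.numeric(doc$wall_height_cm),
               as.numeric(doc$passage_width_cm),
               rois, as.numeric(doc$frame_rate_hz))
}
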