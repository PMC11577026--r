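#' Dual-color urine-mark quantification
#'
#' After the territorial challenge each pair member carries a different
#' systemic dye (fluorescein, excreted yellow-green, or erythrosin b,
#' excreted pink-red), so the urine marks of the two animals can be told
#' apart on a single photograph of the arena floor. Marks are segmented by a
#' deterministic hue/saturation rule classifier after white-balance
#' normalization, speckles below a minimum blob area are removed, and each
#' animal's marking is reported as a percentage of the arena floor area.
#'
#' Dye protocol metadata (doses, latency, persistence) are carried as
#' constants in [dye_protocol] and play no computational role.
#'
#' @name marking
NULL

#' Dye protocol constants
#'
#' Metadata of the dual-dye protocol: fluorescein 39 mg/kg i.p., erythrosin b
#' 54 mg/kg s.c.; dyes become visible in urine about 25 min after injection
#' and remain visible for at least 12 h.
#' @format A list with elements `fluorescein_mg_kg`, `erythrosin_mg_kg`,
#'   `latency_min`, `persistence_h`.
#' @export
dye_protocol <- list(fluorescein_mg_kg = 39, erythrosin_mg_kg = 54,
                     latency_min = 25, persistence_h = 12)

#' Construct a floor image
#'
#' @param rgb Numeric `h x w x 3` array with values in `[0, 1]`.
#' @param px_per_cm Pixels per cm (> 0).
#' @param mask Optional logical `h x w` matrix marking the arena floor;
#'   defaults to the full raster.
#' @return An object of class `floor_image`.
#' @export
floor_image <- function(rgb, px_per_cm, mask = NULL) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] < 3L)
    stop("rgb must be an h x w x 3 array (grayscale input is not supported)")
  rgb <- rgb[, , 1:3, drop = FALSE]
  stopifnot(px_per_cm > 0)
  if (is.null(mask)) {
    mask <- matrix(TRUE, dim(rgb)[1], dim(rgb)[2])
  } else {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(rgb)[1:2]))
      stop("mask dimensions must match the raster")
    mask <- mask & !is.na(mask)
  }
  structure(list(rgb = rgb, px_per_cm = as.numeric(px_per_cm), mask = mask),
            class = "floor_image")
}

#' @export
print.floor_image <- function(x, ...) {
  cat(sprintf("<floor_image> %d x %d px @ %g px/cm, mask covers %.1f%%\n",
              dim(x$rgb)[1], dim(x$rgb)[2], x$px_per_cm,
              100 * mean(x$mask)))
  invisible(x)
}

#' Read / write floor images as PNG
#'
#' @param path PNG path.
#' @param px_per_cm Scale stamped on the image on read.
#' @param mask Optional mask (see [floor_image()]).
#' @param image A [floor_image()].
#' @return `read_floor_image()` a [floor_image()]; `write_floor_image()`
#'   `path`, invisibly.
#' @export
read_floor_image <- function(path, px_per_cm, mask = NULL) {
  a <- png::readPNG(path)
  if (length(dim(a)) != 3L)
    stop("grayscale PNG: dye segmentation needs an RGB image")
  floor_image(a, px_per_cm, mask)
}

#' @rdname read_floor_image
#' @export
write_floor_image <- function(image, path) {
  stopifnot(inherits(image, "floor_image"))
  png::writePNG(image$rgb, path)
  invisible(path)
}

# label 8-connected components of a logical matrix; 0 = background
label_components <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  todo <- which(fg)
  if (!length(todo)) return(lab)
  offs <- as.integer(c(-1, 1, -nr, nr, -nr - 1, -nr + 1, nr - 1, nr + 1))
  row_of <- function(i) ((i - 1L) %% nr) + 1L
  cur <- 0L
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      cand <- rep(frontier, each = 8L) + offs
      fr <- rep(row_of(frontier), each = 8L)
      # drop wrap-arounds across matrix columns and out-of-range indices
      ok <- cand >= 1L & cand <= nr * nc & abs(row_of(cand) - fr) <= 1L
      cand <- unique(cand[ok])
      cand <- cand[fg[cand] & lab[cand] == 0L]
      lab[cand] <- cur
      frontier <- cand
    }
  }
  lab
}

#' Segment the two dyes in a floor image
#'
#' Pixels are classified by hue/saturation/value windows after a per-channel
#' white-balance normalization (each channel is scaled so the bright floor
#' background maps to white). Yellow-green pixels become fluorescein,
#' pink-red pixels erythrosin; a pixel satisfying both windows is assigned to
#' the nearer hue centroid. Connected blobs (8-connectivity) smaller than
#' `min_blob_cm2` are removed per dye. An optional externally computed
#' per-pixel probability raster can replace the rule classifier via
#' `probabilities`.
#'
#' @param image A [floor_image()].
#' @param fluorescein_hue,erythrosin_hue Hue windows in `[0, 1]` (erythrosin's
#'   window wraps around 1 when `min > max`).
#' @param sat_min,val_min Minimum saturation and value for a dye pixel.
#' @param min_blob_cm2 Minimum retained blob area (default 0.05 cm^2).
#' @param probabilities Optional `h x w x 2` array of per-pixel dye
#'   probabilities (fluorescein, erythrosin); pixels are labeled by the
#'   larger probability where it exceeds 0.5, and the hue rules are skipped.
#' @return Integer `h x w` label matrix: 0 background, 1 fluorescein,
#'   2 erythrosin (class `dye_labels`, with the scale kept in attribute
#'   `px_per_cm`).
#' @export
segment_dyes <- function(image,
                         fluorescein_hue = c(0.10, 0.33),
                         erythrosin_hue = c(0.83, 0.05),
                         sat_min = 0.25, val_min = 0.15,
                         min_blob_cm2 = 0.05,
                         probabilities = NULL) {
  stopifnot(inherits(image, "floor_image"))
  dims <- dim(image$rgb)[1:2]
  if (is.null(probabilities)) {
    # white balance: scale channels so the bright background is neutral
    rgbm <- apply(image$rgb, 3, identity)  # (h*w) x 3
    bg <- apply(rgbm[as.vector(image$mask), , drop = FALSE], 2,
                stats::quantile, probs = 0.95, names = FALSE)
    bg[bg < 1e-3] <- 1e-3
    rgbm <- sweep(rgbm, 2, bg, "/")
    rgbm[rgbm > 1] <- 1
    hsv <- grDevices::rgb2hsv(t(rgbm), maxColorValue = 1)
    h <- hsv[1, ]; s <- hsv[2, ]; v <- hsv[3, ]
    in_window <- function(hh, w) {
      if (w[1] <= w[2]) hh >= w[1] & hh <= w[2]
      else hh >= w[1] | hh <= w[2]  # wraps through 1
    }
    strong <- s >= sat_min & v >= val_min
    fl <- strong & in_window(h, fluorescein_hue)
    er <- strong & in_window(h, erythrosin_hue)
    both <- fl & er
    if (any(both)) {
      circ_dist <- function(a, b) pmin(abs(a - b), 1 - abs(a - b))
      fl_c <- mean(fluorescein_hue)
      er_c <- (erythrosin_hue[1] +
               (1 + erythrosin_hue[2] - erythrosin_hue[1]) / 2) %% 1
      to_fl <- circ_dist(h[both], fl_c) <= circ_dist(h[both], er_c)
      fl[both] <- to_fl
      er[both] <- !to_fl
    }
    lab <- matrix(0L, dims[1], dims[2])
    lab[matrix(fl, dims[1], dims[2])] <- 1L
    lab[matrix(er, dims[1], dims[2])] <- 2L
  } else {
    if (!identical(dim(probabilities)[1:2], dims) ||
        dim(probabilities)[3] != 2L)
      stop("probabilities must be an h x w x 2 array")
    pf <- probabilities[, , 1]; pe <- probabilities[, , 2]
    lab <- matrix(0L, dims[1], dims[2])
    lab[pf > 0.5 & pf >= pe] <- 1L
    lab[pe > 0.5 & pe > pf] <- 2L
  }
  lab[!image$mask] <- 0L
  min_px <- max(1L, as.integer(round(min_blob_cm2 * image$px_per_cm^2)))
  if (min_px > 1L) {
    for (d in 1:2) {
      comp <- label_components(lab == d)
      if (max(comp) > 0L) {
        sizes <- tabulate(comp[comp > 0L])
        drop <- which(sizes < min_px)
        if (length(drop)) lab[comp %in% drop] <- 0L
      }
    }
  }
  structure(lab, class = c("dye_labels", class(lab)),
            px_per_cm = image$px_per_cm)
}

#' Percent of arena area marked per dye
#'
#' For each dye, 100 x (labeled pixels inside the mask) / (mask pixels),
#' plus blob counts and blob size distributions from 8-connected components.
#'
#' @param labels Label matrix from [segment_dyes()].
#' @param mask Logical arena mask aligned with `labels`.
#' @return An object of class `mark_quant`: list with `pixels` (named counts),
#'   `percent` (named percentages), `blob_count`, `blob_sizes_px` (list of
#'   per-blob pixel counts per dye) and `mask_px`.
#' @export
percent_marked_area <- function(labels, mask = NULL) {
  lab <- unclass(labels)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(lab), ncol(lab))
  mask <- as.matrix(mask) & !is.na(as.matrix(mask))
  if (!identical(dim(mask), dim(lab)))
    stop("mask dimensions must match the label raster")
  total <- sum(mask)
  if (total == 0L) stop("empty arena mask")
  dyes <- c(fluorescein = 1L, erythrosin = 2L)
  pixels <- vapply(dyes, function(d) sum(lab == d & mask), 0L)
  blobs <- lapply(dyes, function(d) {
    comp <- label_components(lab == d & mask)
    if (max(comp) == 0L) integer(0) else tabulate(comp[comp > 0L])
  })
  structure(list(pixels = pixels,
                 percent = 100 * pixels / total,
                 blob_count = vapply(blobs, length, 0L),
                 blob_sizes_px = blobs,
                 mask_px = total),
            class = "mark_quant")
}

#' @export
print.mark_quant <- function(x, ...) {
  cat(sprintf(paste0("<mark_quant> fluorescein %.2f%% (%d blobs), ",
                     "erythrosin %.2f%% (%d blobs) of %d mask px\n"),
              x$percent["fluorescein"], x$blob_count["fluorescein"],
              x$percent["erythrosin"], x$blob_count["erythrosin"],
              x$mask_px))
  invisible(x)
}

#' Correlate urine marking with the territorial behaviors
#'
#' Appends each mouse's marked-area percentage as an eighth variable to the
#' seven-behavior correlation analysis and reuses [behavior_correlations()].
#'
#' @param marking Data frame with columns `mouse_id` and `marked_pct`.
#' @param mat A [behavior_matrix()] covering the same mice.
#' @param ... Passed to [behavior_correlations()].
#' @return A `behavior_correlations` object over the 8 variables.
#' @export
marking_vs_behavior <- function(marking, mat, ...) {
  stopifnot(all(c("mouse_id", "marked_pct") %in% names(marking)))
  mat <- behavior_matrix(mat)
  unmatched <- setdiff(mat$mouse_id, marking$mouse_id)
  if (length(unmatched))
    stop("no marking data for mice: ", paste(unmatched, collapse = ", "))
  m <- as.matrix(mat[, BEHAVIOR_COLS])
  m <- cbind(m, marked_pct = marking$marked_pct[
    match(mat$mouse_id, marking$mouse_id)])
  behavior_correlations(m, ...)
}
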