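# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately naive (per-point loops, brute force,
# closed forms) and shares no code with the package implementation.

# ray-casting point-in-polygon with explicit boundary handling
pip_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  on_boundary <- function(x, y) {
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      x1 <- poly[i, 1]; y1 <- poly[i, 2]
      x2 <- poly[j, 1]; y2 <- poly[j, 2]
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) < 1e-9 &&
          x >= min(x1, x2) - 1e-9 && x <= max(x1, x2) + 1e-9 &&
          y >= min(y1, y2) - 1e-9 && y <= max(y1, y2) + 1e-9)
        return(TRUE)
    }
    FALSE
  }
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    if (on_boundary(x, y)) return(TRUE)
    crossings <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- poly[i, 2]; y2 <- poly[j, 2]
      if ((y1 > y) != (y2 > y)) {
        xi <- poly[i, 1] + (y - y1) / (y2 - y1) * (poly[j, 1] - poly[i, 1])
        if (x < xi) crossings <- crossings + 1L
      }
    }
    crossings %% 2L == 1L
  }, TRUE)
}

# run-length bouts of a logical vector: list of (start0, end0) half-open
rle_bouts_oracle <- function(inside) {
  out <- list()
  i <- 1L
  while (i <= length(inside)) {
    if (isTRUE(inside[i])) {
      j <- i
      while (j < length(inside) && isTRUE(inside[j + 1L])) j <- j + 1L
      out[[length(out) + 1L]] <- c(i - 1L, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# brute-force centered windowed mean (partial windows at edges)
winmean_oracle <- function(v, w) {
  h <- (w - 1L) %/% 2L
  vapply(seq_along(v), function(i) {
    seg <- v[max(1L, i - h):min(length(v), i + h)]
    mean(seg[is.finite(seg)])
  }, 0)
}

# all perfect matchings of indices 1..n as list of 2-col matrices
matchings_oracle <- function(n) {
  if (n == 0L) return(list(matrix(integer(0), 0, 2)))
  first <- 1L
  out <- list()
  for (b in 2:n) {
    rest <- setdiff(seq_len(n), c(first, b))
    if (!length(rest)) {
      out[[length(out) + 1L]] <- rbind(c(first, b))
    } else {
      sub <- matchings_oracle(length(rest))
      for (m in sub)
        out[[length(out) + 1L]] <- rbind(c(first, b),
                                         matrix(rest[m], ncol = 2))
    }
  }
  out
}

# a single-mouse track whose middle back follows `pts` (n x 2, cm); all
# other body parts ride on the same point, confidence 1
scripted_track <- function(pts, fps = 45, mouse_id = "m", parts = c(
    "nose", "right_ear", "left_ear", "middle_back", "right_side",
    "left_side", "tail_base", "tail_end")) {
  pts <- as.matrix(pts)
  xm <- matrix(rep(pts[, 1], length(parts)), ncol = length(parts),
               dimnames = list(NULL, parts))
  ym <- matrix(rep(pts[, 2], length(parts)), ncol = length(parts),
               dimnames = list(NULL, parts))
  pose_track(mouse_id, fps, xm, ym)
}

# minimal behavior matrices with random or supplied behavior values
mk_matrix <- function(vals, n = nrow(vals)) {
  df <- data.frame(mouse_id = paste0("m", seq_len(n)),
                   pair_id = rep(paste0("p", seq_len(ceiling(n / 2))),
                                 each = 2)[seq_len(n)])
  cbind(df, as.data.frame(vals))
}

rand_matrix <- function(n, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(n * 7), n, 7,
                 dimnames = list(NULL, territr:::BEHAVIOR_COLS))
  mk_matrix(vals)
}

# constant-position track of n frames at point p
parked_track <- function(p, n, fps = 45, mouse_id = "m") {
  scripted_track(matrix(rep(p, each = n), ncol = 2), fps, mouse_id)
}

# piecewise-constant track from a schedule: data.frame(x, y, frames)
schedule_track <- function(schedule, fps = 45, mouse_id = "m") {
  pts <- do.call(rbind, lapply(seq_len(nrow(schedule)), function(i)
    matrix(rep(c(schedule$x[i], schedule$y[i]), each = schedule$frames[i]),
           ncol = 2)))
  scripted_track(pts, fps, mouse_id)
}
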