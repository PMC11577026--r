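FLUO <- c(0.80, 0.88, 0.25)
ERY <- c(0.93, 0.35, 0.60)

# plain synthetic raster: white floor with solid rectangular dye patches
patch_image <- function(nr = 60, nc = 60, patches = list(), px_per_cm = 2) {
  img <- array(rep(c(0.95, 0.94, 0.93), each = nr * nc), c(nr, nc, 3))
  for (p in patches) {
    col <- if (p$dye == 1) FLUO else ERY
    for (ch in 1:3)
      img[p$rows, p$cols, ch] <- col[ch]
  }
  floor_image(img, px_per_cm)
}

test_that("the dye segmenter needs color and ignores clean backgrounds", {
  expect_error(floor_image(matrix(0.5, 10, 10), 2), "h x w x 3")
  img <- patch_image()
  lab <- segment_dyes(img)
  expect_equal(sum(lab != 0), 0)
})

test_that("solid patches are recovered pixel-exactly", {
  img <- patch_image(patches = list(
    list(dye = 1, rows = 11:20, cols = 21:30),   # 100 px fluorescein
    list(dye = 2, rows = 41:45, cols = 11:20)))  # 50 px erythrosin
  lab <- segment_dyes(img)
  expect_equal(sum(lab == 1), 100)
  expect_equal(sum(lab == 2), 50)
  expect_true(all(lab[11:20, 21:30] == 1))
  # low-amplitude noise does not change the labels
  noisy <- img
  set.seed(81)
  noisy$rgb[] <- pmin(1, pmax(0, noisy$rgb +
                                   rnorm(length(noisy$rgb), 0, 0.01)))
  expect_equal(unclass(segment_dyes(noisy)), unclass(lab))
})

test_that("blob cleanup removes specks below the minimum area", {
  img <- patch_image(patches = list(
    list(dye = 1, rows = 5:14, cols = 5:14),  # 100 px blob
    list(dye = 1, rows = 30, cols = 30)))     # single-pixel speck
  # at 10 px/cm (100 px/cm^2) the 0.05 cm^2 floor is 5 px: the speck goes
  img$px_per_cm <- 10
  lab <- segment_dyes(img)
  expect_equal(sum(lab == 1), 100)
  expect_equal(lab[30, 30], 0L)
})

test_that("connected components use 8-connectivity", {
  img <- patch_image(patches = list(
    list(dye = 1, rows = 10, cols = 10),
    list(dye = 1, rows = 11, cols = 11),   # diagonal neighbor: same blob
    list(dye = 1, rows = 20, cols = 20)))  # separate blob
  lab <- segment_dyes(img)
  q <- percent_marked_area(lab)
  expect_equal(unname(q$blob_count["fluorescein"]), 2L)
  expect_equal(sort(q$blob_sizes_px$fluorescein), c(1L, 2L))
})

test_that("marked-area percentages are mask-relative", {
  nr <- 40; nc <- 40
  # a label raster saturated with one dye scores 100% of the mask
  full <- matrix(1L, nr, nc)
  q <- percent_marked_area(full)
  expect_equal(unname(q$percent["fluorescein"]), 100)
  expect_equal(unname(q$percent["erythrosin"]), 0)
  lab <- full
  q0 <- percent_marked_area(segment_dyes(patch_image()))
  expect_equal(unname(q0$percent), c(0, 0))
  expect_error(percent_marked_area(lab, matrix(FALSE, nr, nc)), "empty")
  expect_error(percent_marked_area(lab, matrix(TRUE, 3, 3)), "dimensions")
  # rendered fixture: percent matches the drawn ground truth
  rmi <- render_mark_image(c(2, 0.5), px_per_cm = 2, seed = 5)
  q2 <- percent_marked_area(segment_dyes(rmi$image), rmi$image$mask)
  truth_pct <- 100 * c(sum(rmi$truth == 1), sum(rmi$truth == 2)) /
    length(rmi$truth)
  expect_equal(unname(q2$percent), truth_pct, tolerance = 0.02)
})

test_that("quantification is invariant to quarter-turn rotation", {
  rmi <- render_mark_image(c(1.5, 0.8), px_per_cm = 2, seed = 9)
  lab <- segment_dyes(rmi$image)
  q <- percent_marked_area(lab, rmi$image$mask)
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  rgb_r <- array(0, c(dim(rmi$image$rgb)[2], dim(rmi$image$rgb)[1], 3))
  for (ch in 1:3) rgb_r[, , ch] <- rot90(rmi$image$rgb[, , ch])
  img_r <- floor_image(rgb_r, 2, rot90(rmi$image$mask))
  q_r <- percent_marked_area(segment_dyes(img_r), img_r$mask)
  expect_equal(q_r$percent, q$percent)
  expect_equal(q_r$blob_count, q$blob_count)
})

test_that("marked area grows monotonically as thresholds loosen", {
  rmi <- render_mark_image(c(2, 1), px_per_cm = 2, seed = 13)
  tight <- segment_dyes(rmi$image, sat_min = 0.4)
  mid <- segment_dyes(rmi$image, sat_min = 0.25)
  loose <- segment_dyes(rmi$image, sat_min = 0.1)
  counts <- vapply(list(tight, mid, loose), function(l) sum(l != 0), 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("floor images round-trip through PNG", {
  rmi <- render_mark_image(c(1, 0.5), px_per_cm = 2, seed = 17)
  f <- withr::local_tempfile(fileext = ".png")
  write_floor_image(rmi$image, f)
  back <- read_floor_image(f, px_per_cm = 2)
  expect_equal(back$rgb, rmi$image$rgb, tolerance = 1 / 255)
})

test_that("marking correlates with behaviors through the shared machinery", {
  set.seed(91)
  vals <- matrix(rnorm(20 * 7), 20, 7,
                 dimnames = list(NULL, territr:::BEHAVIOR_COLS))
  bm <- behavior_matrix(data.frame(
    mouse_id = paste0("m", 1:20), pair_id = rep(paste0("p", 1:10), each = 2),
    vals))
  marking <- data.frame(mouse_id = bm$mouse_id,
                        marked_pct = bm$hiding_frac)
  mc <- marking_vs_behavior(marking, bm)
  expect_equal(mc$r["marked_pct", "hiding_frac"], 1)
  # constant marking is flagged undefined
  mc2 <- marking_vs_behavior(transform(marking, marked_pct = 2), bm)
  expect_true("marked_pct" %in% mc2$constant)
  expect_error(marking_vs_behavior(marking[-1, ], bm), "no marking data")
})
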