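layout <- default_layout()

test_that("dwell bouts are maximal runs on half-open frame intervals", {
  mk_labels <- function(inside) {
    tr <- schedule_track(data.frame(
      x = ifelse(inside, 4, 60), y = ifelse(inside, 4, 30),
      frames = 1))
    roi_labels(tr, layout)
  }
  b <- dwell_bouts(mk_labels(c(TRUE, TRUE, FALSE, TRUE)), "c1_corner_nw")
  expect_equal(b$start_frame, c(0, 3))
  expect_equal(b$end_frame, c(2, 4))
  expect_equal(b$duration_s, c(2, 1) / 45)
  expect_equal(nrow(dwell_bouts(mk_labels(rep(FALSE, 5)), "c1_corner_nw")), 0)
  # random membership equals the run-length-encoding oracle
  set.seed(13)
  inside <- runif(500) < 0.4
  b2 <- dwell_bouts(mk_labels(inside), "c1_corner_nw")
  oracle <- rle_bouts_oracle(inside)
  expect_equal(nrow(b2), length(oracle))
  for (i in seq_along(oracle)) {
    expect_equal(b2$start_frame[i], oracle[[i]][1])
    expect_equal(b2$end_frame[i], oracle[[i]][2])
  }
})

test_that("the sub-second occupancy filter keeps exactly 1 s bouts", {
  mk <- function(lens) {
    starts <- if (length(lens)) cumsum(c(0, head(lens, -1) * 2)) else integer(0)
    df <- data.frame(roi_name = rep("r", length(lens)),
                     start_frame = starts, end_frame = starts + lens,
                     duration_s = lens / 45, stringsAsFactors = FALSE)
    attr(df, "frame_rate_hz") <- 45
    df
  }
  # 0.5 s (22 frames) discarded, 2.0 s (90 frames) kept
  f <- min_dwell_filter(mk(c(22L, 90L)))
  expect_equal(f$end_frame - f$start_frame, 90L)
  # a bout of exactly 1.0 s (45 frames) is retained
  expect_equal(nrow(min_dwell_filter(mk(45L))), 1)
  expect_equal(nrow(min_dwell_filter(mk(44L))), 0)
  expect_equal(nrow(min_dwell_filter(mk(integer(0)))), 0)
  # idempotent, and monotone in min_s (larger threshold -> subset)
  set.seed(2)
  b <- mk(sample(10:100, 20))
  f1 <- min_dwell_filter(b, 1)
  expect_equal(min_dwell_filter(f1, 1), f1)
  f2 <- min_dwell_filter(b, 1.5)
  expect_true(all(f2$start_frame %in% f1$start_frame))
})

test_that("hiding time sums filtered refuge occupancy once per frame", {
  # parked in one corner for a whole 20-min window -> 1200 s
  tr <- parked_track(c(4, 4), 20 * 60 * 45)
  expect_equal(hiding_time(tr, layout), 1200)
  # never in a hiding ROI -> 0 (cage center is hiding, so park on open floor)
  tr0 <- parked_track(c(30, 30), 45 * 30)
  expect_equal(hiding_time(tr0, layout), 0)
  # scripted schedule: alternating corner / open-floor bouts, some sub-second
  sched <- data.frame(
    x = c(4, 30, 116, 30, 4, 30, 60), y = c(4, 30, 4, 30, 56, 30, 30),
    frames = c(90, 200, 44, 100, 135, 50, 90))
  # corner bouts: 90 (kept), 44 (< 1 s, dropped), 135 (kept); cage-center 90
  tr2 <- schedule_track(sched)
  expect_equal(hiding_time(tr2, layout), (90 + 135 + 90) / 45)
  # per-mouse vector interface
  expect_equal(unname(hiding_time(list(a = tr, b = tr0), layout)), c(1200, 0))
})

test_that("exploration subtracts refuge time inside the opponent side", {
  # mouse from compartment 1 never leaving it -> 0
  tr <- parked_track(c(30, 30), 45 * 60)
  expect_equal(exploration_time(tr, layout, 1), 0)
  # 300 s in the opponent compartment of which 100 s in its corners -> 200 s
  sched <- data.frame(x = c(30, 30, 4), y = c(30, 90, 64),
                      frames = c(450, 200 * 45, 100 * 45))
  tr2 <- schedule_track(sched)
  expect_equal(exploration_time(tr2, layout, 1), 200)
  # own-compartment refuges do not count against exploration
  expect_equal(exploration_time(tr2, layout, 2), 450 / 45)
})

test_that("proximity needs closeness and shared ROI, and is symmetric", {
  n <- 60 * 45
  a <- parked_track(c(30, 30), n, mouse_id = "a")
  b <- parked_track(c(35, 30), n, mouse_id = "b")  # 5 cm apart, same side
  expect_equal(proximity_time(a, b, layout), 60)
  # 5 cm apart but across the dividing wall -> different compartments -> 0
  c1 <- parked_track(c(30, 57.5), n, mouse_id = "a")
  c2 <- parked_track(c(30, 62.5), n, mouse_id = "b")
  expect_equal(proximity_time(c1, c2, layout), 0)
  # strict threshold: exactly 10 cm apart is not "less than 10 cm"
  d2 <- parked_track(c(40, 30), n, mouse_id = "b")
  expect_equal(proximity_time(a, d2, layout), 0)
  # random-walk pair equals a frame-by-frame brute-force recomputation
  set.seed(31)
  na <- 450
  pa <- cbind(runif(na, 1, 119), runif(na, 1, 59))
  pb <- cbind(pmin(119, pmax(1, pa[, 1] + rnorm(na, 0, 8))),
              pmin(59, pmax(1, pa[, 2] + rnorm(na, 0, 8))))
  ta <- scripted_track(pa, mouse_id = "a")
  tb <- scripted_track(pb, mouse_id = "b")
  got <- proximity_time(ta, tb, layout, min_s = 0)
  prox_set <- proximity_rois(layout)
  oracle <- 0
  for (i in seq_len(na)) {
    d <- sqrt(sum((pa[i, ] - pb[i, ])^2))
    shared <- FALSE
    for (nm in prox_set) {
      poly <- layout$rois[[nm]]$polygon
      if (pip_oracle(pa[i, 1], pa[i, 2], poly) &&
          pip_oracle(pb[i, 1], pb[i, 2], poly)) shared <- TRUE
    }
    if (d < 10 && shared) oracle <- oracle + 1 / 45
  }
  expect_equal(got, oracle)
  expect_equal(got, proximity_time(tb, ta, layout, min_s = 0))
})

test_that("occupancy conserves time and is translation invariant", {
  # hiding + non-hiding frames partition the window for a never-missing track
  set.seed(17)
  sched <- data.frame(x = runif(12, 2, 118), y = runif(12, 2, 58),
                      frames = sample(30:150, 12, replace = TRUE))
  tr <- schedule_track(sched)
  lab <- roi_labels(tr, layout)
  occ <- territr:::filtered_occupancy(lab, hiding_rois(layout), min_s = 0)
  n <- sum(sched$frames)
  expect_equal(sum(occ) + sum(!occ), n)
  expect_equal(hiding_time(tr, layout, min_s = 0) +
                 (n - sum(occ)) / 45, n / 45)
  # rigid translation of layout and track together leaves metrics unchanged
  shift <- c(13.5, -7.25)
  rois2 <- lapply(unname(layout$rois), function(r)
    roi(r$name, r$category, sweep(r$polygon, 2, -shift), r$compartment_id))
  l2 <- suppressWarnings(structure(
    utils::modifyList(unclass(layout), list(rois = NULL)),
    class = "arena_layout"))
  l2$rois <- rois2
  names(l2$rois) <- names(layout$rois)
  tr2 <- scripted_track(sweep(do.call(
    rbind, lapply(seq_len(nrow(sched)), function(i)
      matrix(rep(c(sched$x[i], sched$y[i]), each = sched$frames[i]),
             ncol = 2))), 2, -shift))
  expect_equal(hiding_time(tr2, l2), hiding_time(tr, layout))
  expect_equal(exploration_time(tr2, l2, 1), exploration_time(tr, layout, 1))
  expect_equal(locomotion(tr2), locomotion(tr))
})

test_that("trajectory metrics bundle matches its component functions", {
  set.seed(23)
  sched <- data.frame(x = runif(8, 2, 118), y = runif(8, 2, 118),
                      frames = sample(50:200, 8, replace = TRUE))
  tr <- schedule_track(sched)
  tm <- trajectory_metrics(tr, layout, own_compartment_id = 1)
  expect_equal(tm$locomotion_cm, locomotion(tr))
  expect_equal(tm$hiding_s, hiding_time(tr, layout))
  expect_equal(tm$exploration_s, exploration_time(tr, layout, 1))
  expect_true(all(tm$per_roi_dwell_s >= 0))
  # exploration is bounded by time in the opponent compartment
  lab <- roi_labels(tr, layout)
  opp <- territr:::filtered_occupancy(lab, "compartment2", 1)
  expect_lte(tm$exploration_s, sum(opp) / 45)
})
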