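mk_events <- function(mouse_id, behavior, onsets, dur = 2) {
  n <- length(onsets)
  ethogram_events(data.frame(mouse_id = rep_len(mouse_id, n),
                             behavior = rep_len(behavior, n),
                             onset_s = onsets, offset_s = onsets + dur))
}

test_that("event tables enforce the behavior vocabulary", {
  expect_error(mk_events("a", "groom", 10), "unknown behaviors")
  expect_error(ethogram_events(data.frame(mouse_id = "a", behavior = "attack",
                                          onset_s = 5, offset_s = 4)),
               "offsets")
  f <- withr::local_tempfile(fileext = ".csv")
  ev <- mk_events("a", "attack", c(10, 20, 30))
  write_events(ev, f)
  expect_equal(read_events(f)$onset_s, c(10, 20, 30))
})

test_that("behavior counts use onset-based window assignment", {
  early <- c(0, 1200)
  expect_equal(behavior_counts(mk_events("a", "attack", numeric(0)),
                               "a", "attack", early), 0)
  ev <- mk_events("a", "attack", c(60, 300, 1140))
  expect_equal(behavior_counts(ev, "a", "attack", early), 3)
  # an event straddling the boundary counts once, in its onset window
  ev2 <- mk_events("a", "attack", 1199, dur = 10)
  expect_equal(behavior_counts(ev2, "a", "attack", early), 1)
  expect_equal(behavior_counts(ev2, "a", "attack", c(1200, 2400)), 0)
  expect_error(behavior_counts(ev, "a", "digging", early), "unknown behavior")
  # random event set equals a brute-force filter-and-count
  set.seed(41)
  n <- 400
  ev3 <- ethogram_events(data.frame(
    mouse_id = sample(c("a", "b"), n, TRUE),
    behavior = sample(c("attack", "chase", "flight", "upright"), n, TRUE),
    onset_s = runif(n, 0, 7200), offset_s = 7200))
  ev3$offset_s <- ev3$onset_s + 1
  for (w in list(c(0, 1200), c(6000, 7200))) {
    got <- behavior_counts(ev3, "a", "chase", w)
    brute <- 0
    for (i in seq_len(n))
      if (ev3$mouse_id[i] == "a" && ev3$behavior[i] == "chase" &&
          ev3$onset_s[i] >= w[1] && ev3$onset_s[i] < w[2])
        brute <- brute + 1
    expect_equal(got, brute)
  }
})

test_that("subinterval counts conserve the phase total", {
  set.seed(43)
  ev <- mk_events("a", "flight", runif(100, 0, 1200))
  subs <- lapply(0:1, function(k) c(k * 600, (k + 1) * 600))
  parts <- vapply(subs, function(w) behavior_counts(ev, "a", "flight", w), 0)
  expect_equal(sum(parts), behavior_counts(ev, "a", "flight", c(0, 1200)))
})

test_that("pair differences are antisymmetric and optionally absolute", {
  bm <- data.frame(mouse_id = c("a", "b"), pair_id = "p1",
                   attacks = c(7, 2), flights = c(3, 3))
  expect_equal(pair_difference(bm, "p1", "flights"), 0)
  expect_equal(pair_difference(bm, "p1", "attacks", absolute = TRUE), 5)
  swapped <- bm[2:1, ]
  expect_equal(pair_difference(swapped, "p1", "attacks"),
               -pair_difference(bm, "p1", "attacks"))
  expect_error(pair_difference(bm[1, ], "p1", "attacks"), "exactly 2")
})

test_that("difference evolution reports dominant minus subordinate", {
  ranks <- data.frame(pair_id = "p1", dominant = "a", subordinate = "b")
  # hand-scripted per-subinterval counts
  vals <- expand.grid(mouse_id = c("a", "b"), subinterval = 1:4,
                      behavior = "attacks", stringsAsFactors = FALSE)
  vals$pair_id <- "p1"
  vals$value <- c(2, 2, 3, 2, 9, 2, 12, 1)  # a then b per subinterval
  ev <- difference_evolution(vals, ranks)
  expect_equal(ev$diff[order(ev$subinterval)], c(0, 1, 7, 11))
  expect_error(difference_evolution(transform(vals, pair_id = "p9"), ranks),
               "no dominance labels")
  # a planted ramp makes the attack difference grow across subintervals
  set.seed(47)
  spec <- cohort_spec(n_pairs = 6, divergence = 1)
  diffs <- matrix(0, 6, 4)
  for (i in 1:6) {
    pr <- simulate_pair(spec, 700 + i, paste0("p", i))
    dom <- pr$truth$dominant
    sub <- setdiff(names(pr$tracks), dom)
    for (k in 1:4) {
      w <- c((k - 1) * 1800, k * 1800)
      diffs[i, k] <- behavior_counts(pr$events, dom, "attack", w) -
        behavior_counts(pr$events, sub, "attack", w)
    }
  }
  m <- colMeans(diffs)
  expect_true(all(diff(m) > 0))
  # null cohort: no systematic dominant advantage
  spec0 <- cohort_spec(n_pairs = 6, divergence = 0)
  d0 <- vapply(1:10, function(i) {
    pr <- simulate_pair(spec0, 900 + i, "p")
    dom <- pr$truth$dominant
    sub <- setdiff(names(pr$tracks), dom)
    behavior_counts(pr$events, dom, "attack", c(0, 7200)) -
      behavior_counts(pr$events, sub, "attack", c(0, 7200))
  }, 0)
  expect_lt(abs(mean(d0)), 15)  # ~60 attacks per mouse; parity within noise
})

test_that("flight alignment finds the steepest-slope frame", {
  fps <- 45
  n <- 120 * fps
  # constant speed: zero slope everywhere, tie broken to the earliest frame
  sp <- list(m = rep(5, n))
  fl <- data.frame(mouse_id = "m", onset_s = 60)
  k <- flight_aligned_kinematics(fl, sp, rep(20, n), fps)
  # earliest frame of the search window with a defined centered slope
  expect_equal(k$centers$center_frame, (60 - 30) * fps + 2)
  # step-ramp: known ramp onset recovered to +/- 1 frame
  ramp_frame <- 70 * fps
  v <- rep(4, n)
  v[ramp_frame:(ramp_frame + 22)] <- 4 + (0:22) * 2.5
  v[(ramp_frame + 23):(ramp_frame + 60)] <- 4
  k2 <- flight_aligned_kinematics(data.frame(mouse_id = "m", onset_s = 69),
                                  list(m = v), rep(20, n), fps)
  # steepest slope of the smoothed ramp sits mid-ramp; the detected center
  # must lie inside the ramp
  expect_gte(k2$centers$center_frame, ramp_frame - 1)
  expect_lte(k2$centers$center_frame, ramp_frame + 23)
  # replicated identical flights: SEM identically 0, mean = single trace
  fl10 <- data.frame(mouse_id = "m", onset_s = rep(69, 10))
  k10 <- flight_aligned_kinematics(fl10, list(m = v), rep(20, n), fps)
  k1 <- flight_aligned_kinematics(fl10[1, ], list(m = v), rep(20, n), fps)
  expect_equal(k10$speed_mean, k1$speed_mean)
  expect_equal(k10$speed_sem, rep(0, length(k10$speed_sem)))
  expect_equal(k10$dist_mean, k1$dist_mean)
  # invariant to flight ordering
  set.seed(51)
  flm <- data.frame(mouse_id = "m", onset_s = runif(8, 40, 80))
  ka <- flight_aligned_kinematics(flm, list(m = v), rep(20, n), fps)
  kb <- flight_aligned_kinematics(flm[sample(8), ], list(m = v),
                                  rep(20, n), fps)
  expect_equal(ka$speed_mean, kb$speed_mean)
  expect_equal(ka$speed_sem, kb$speed_sem)
  # fully-outside window is skipped and logged
  kout <- flight_aligned_kinematics(
    data.frame(mouse_id = "m", onset_s = 1e6), list(m = v), rep(20, n), fps)
  expect_equal(kout$skipped, 1L)
})

test_that("slope detection mirrors under time reversal", {
  fps <- 45
  n <- 100 * fps
  v <- rep(3, n)
  up <- (50 * fps):(50 * fps + 20)
  v[up] <- 3 + seq(0, 40, length.out = 21)
  v[(max(up) + 1):n] <- 43
  k <- flight_aligned_kinematics(data.frame(mouse_id = "m", onset_s = 50),
                                 list(m = v), rep(1, n), fps)
  # time-reversed, vertically mirrored signal: the rising edge sits at the
  # mirrored position, up to the width of the slope tie region
  vr <- (3 + 43) - rev(v)
  kr <- flight_aligned_kinematics(data.frame(mouse_id = "m", onset_s = 50),
                                  list(m = vr), rep(1, n), fps)
  expect_lte(abs(kr$centers$center_frame -
                 (n + 1L - k$centers$center_frame)), 4)
})

test_that("attack penetrance counts pairs with any attack", {
  pairs <- data.frame(mouse_id = paste0("m", 1:6),
                      pair_id = rep(c("p1", "p2", "p3"), each = 2))
  all_fight <- mk_events(paste0("m", c(1, 3, 5)), "attack", c(10, 20, 30))
  expect_equal(attack_penetrance(all_fight, pairs), 1)
  none <- mk_events("m1", "chase", 10)
  expect_equal(attack_penetrance(none, pairs), 0)
  # 11 of 18 pairs -> 11/18
  pairs18 <- data.frame(mouse_id = paste0("m", 1:36),
                        pair_id = rep(paste0("p", 1:18), each = 2))
  ev <- mk_events(paste0("m", seq(1, 22, by = 2)), "attack", 1:11 * 10)
  expect_equal(attack_penetrance(ev, pairs18), 11 / 18)
})
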