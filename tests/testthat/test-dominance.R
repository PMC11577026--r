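test_that("z-scoring pools all mice and flags zero-variance behaviors", {
  bm <- rand_matrix(10)
  bm$chases <- 3  # constant column
  expect_error(zscore_behaviors(bm), "chases")
  # two-value column under the population-SD convention gives -1 / +1
  bm2 <- rand_matrix(2, seed = 2)
  bm2$attacks <- c(0, 2)
  z <- zscore_behaviors(bm2, sd_type = "population")
  expect_equal(unname(z[, "attacks"]), c(-1, 1))
  # every column has mean ~0 and unit sample SD
  z3 <- zscore_behaviors(rand_matrix(40, seed = 3))
  expect_true(all(abs(colMeans(z3)) < 1e-12))
  expect_equal(unname(apply(z3, 2, sd)), rep(1, 7))
})

test_that("the PCA decomposes variance and matches a hand eigen-solve", {
  # perfectly anticorrelated two-variable data: PC1 carries all variance
  x <- c(-2, -1, 0, 1, 2)
  toy <- cbind(a = x, b = -x)
  res <- dominance_pca(toy)
  expect_equal(res$variance_frac[1], 1)
  # variance fractions always sum to 1 and are non-increasing
  res2 <- dominance_pca(zscore_behaviors(rand_matrix(30, seed = 4)))
  expect_equal(sum(res2$variance_frac), 1)
  expect_true(all(diff(res2$variance_frac) <= 1e-12))
  # 3 x 2 toy matrix against a closed-form 2x2 eigen-solve
  m <- cbind(a = c(1, 2, 4), b = c(0, 1, 1))
  mc <- scale(m, scale = FALSE)
  cv <- crossprod(mc) / 2
  tr <- cv[1, 1] + cv[2, 2]
  det <- cv[1, 1] * cv[2, 2] - cv[1, 2]^2
  lam1 <- (tr + sqrt(tr^2 - 4 * det)) / 2
  lam2 <- (tr - sqrt(tr^2 - 4 * det)) / 2
  res3 <- dominance_pca(m)
  expect_equal(unname(res3$sdev^2), c(lam1, lam2))
  expect_equal(res3$variance_frac, c(lam1, lam2) / (lam1 + lam2))
  v1 <- c(cv[1, 2], lam1 - cv[1, 1])
  v1 <- v1 / sqrt(sum(v1^2))
  if (v1[1] < 0) v1 <- -v1  # package orients the first loading positive
  expect_equal(unname(res3$loadings[, 1]), v1)
  # isotropic noise spreads variance roughly evenly over the 7 behaviors
  z <- zscore_behaviors(rand_matrix(600, seed = 5))
  res4 <- dominance_pca(z)
  expect_true(all(abs(res4$variance_frac - 1 / 7) < 0.04))
  expect_error(dominance_pca(matrix(c(1, NA, 2, 3), 2)), "missing")
})

test_that("PC1 scores are stable under row permutation", {
  bm <- rand_matrix(20, seed = 6)
  z <- zscore_behaviors(bm)
  res <- dominance_pca(z)
  perm <- sample(20)
  res_p <- dominance_pca(z[perm, ])
  expect_equal(res_p$scores[rownames(z), 1], res$scores[, 1])
})

test_that("rank assignment labels the higher PC1 member dominant", {
  bm <- rand_matrix(4, seed = 7)
  z <- zscore_behaviors(bm)
  res <- dominance_pca(z)
  res$scores[, 1] <- c(2, -1.5, 0.5, 0.5)
  pairs <- bm[, c("mouse_id", "pair_id")]
  r <- assign_ranks(res, pairs)
  expect_equal(r$dominant[1], "m1")
  expect_equal(r$pc1_diff[1], 3.5)
  expect_true(r$tied[2])
  expect_equal(r$pc1_diff[2], 0)
  res$scores <- res$scores[1:3, ]
  expect_error(assign_ranks(res, pairs), "missing PC1")
})

test_that("re-pairing permutation test matches exhaustive enumeration", {
  # identical values: observed 0 and p = 1
  v <- rep(3, 6)
  r <- repairing_permutation_test(v, rep(1:3, each = 2))
  expect_equal(r$observed, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$method, "exhaustive")
  expect_error(repairing_permutation_test(1:5, c(1, 1, 2, 2, 3)), "even")
  # cohorts of 4: p equals the 3-matching brute-force oracle
  set.seed(61)
  for (rep in 1:5) {
    v4 <- rnorm(4)
    pr <- c(1, 1, 2, 2)
    got <- repairing_permutation_test(v4, pr)
    stats <- vapply(matchings_oracle(4), function(m)
      mean(abs(v4[m[, 1]] - v4[m[, 2]])), 0)
    obs <- mean(abs(c(v4[1] - v4[2], v4[3] - v4[4])))
    expect_equal(sort(got$null), sort(stats))
    expect_equal(got$p_value, mean(stats >= obs - 1e-12))
  }
  # strongly divergent planted pairs (8 pairs of one high + one low value):
  # random matchings rarely reproduce the full high/low split, so the
  # observed mean |difference| is extreme under the sampled null
  v16 <- rep(c(10, -10), 8) + rnorm(16, 0, 0.1)
  rs <- repairing_permutation_test(v16, rep(1:8, each = 2), n_perm = 2000,
                                   seed = 9)
  expect_equal(rs$method, "sampled")
  expect_lte(rs$p_value, 0.05)
  expect_equal(rs$n_permutations, 2000)
  # seeded runs reproduce
  rs2 <- repairing_permutation_test(v16, rep(1:8, each = 2), n_perm = 2000,
                                    seed = 9)
  expect_identical(rs$null, rs2$null)
})

test_that("correlation matrices mask insignificant and undefined cells", {
  bm <- rand_matrix(30, seed = 8)
  bm$flights <- -bm$attacks
  bc <- behavior_correlations(bm)
  expect_equal(unname(diag(bc$r)), rep(1, 7))
  expect_equal(bc$r["attacks", "flights"], -1)
  expect_true(bc$significant["attacks", "flights"])
  # a constant column is undefined and flagged
  bm$chases <- 5
  bc2 <- behavior_correlations(bm)
  expect_true("chases" %in% bc2$constant)
  expect_true(all(is.na(bc2$r["chases", ])))
  # planted correlation recovered within its confidence interval
  set.seed(71)
  n <- 200
  x <- rnorm(n)
  y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(n)
  bc3 <- behavior_correlations(cbind(x = x, y = y))
  ci <- tanh(atanh(bc3$r["x", "y"]) + c(-2, 2) / sqrt(n - 3))
  expect_true(0.8 > ci[1] && 0.8 < ci[2])
})

test_that("group-test wrappers handle degenerate inputs and match ranks", {
  w <- paired_wilcoxon(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$p_value, 1)
  expect_equal(w$statistic, 0)
  kd0 <- kruskal_dunn(rep(c(5, 5, 5), 3), rep(1:3, each = 3))
  expect_lt(kd0$H, 1e-9)
  # textbook toy: H from the rank formula, computed by hand here
  vals <- c(27, 2, 4, 18, 7, 9)
  grp <- rep(c("g1", "g2", "g3"), each = 2)
  kd <- kruskal_dunn(vals, grp)
  rk <- rank(vals)
  N <- 6
  H <- 12 / (N * (N + 1)) *
    sum(tapply(rk, grp, sum)^2 / 2) - 3 * (N + 1)
  expect_equal(kd$H, H)
  expect_equal(nrow(kd$dunn), 3)
  expect_true(all(kd$dunn$p_adj >= kd$dunn$p))
})

test_that("validation indices implement the (a-b)/(a+b) contrast", {
  expect_equal(anxiety_index(10, 10), 0)
  expect_equal(anxiety_index(30, 10), 0.5)
  expect_equal(preference_index(0, 20), -1)
  expect_warning(out <- preference_index(0, 0), "undefined")
  expect_true(is.na(out))
  expect_error(anxiety_index(-1, 5), "non-negative")
})
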