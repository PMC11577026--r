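#' Dominance inference from the seven-behavior matrix
#'
#' Each mouse is summarized by seven behaviors measured in one phase of the
#' territorial challenge: the counts of attacks, chases, flights and upright
#' postures, the locomotion in cm, and the fraction of time spent in
#' exploration and in hiding. Behaviors are z-scored across the pooled cohort
#' (all strains together), a PCA extracts the dominant axes of covariation,
#' and the member of each pair with the higher first-component score is
#' labeled dominant. Whether within-pair differences exceed chance is judged
#' against a null built by randomly re-pairing the whole cohort.
#'
#' @name dominance
NULL

BEHAVIOR_COLS <- c("attacks", "chases", "flights", "uprights",
                   "locomotion_cm", "exploration_frac", "hiding_frac")

#' Validate a behavior matrix
#'
#' @param df One row per mouse with identifier columns `mouse_id`, `pair_id`
#'   (each pair id on exactly two rows) and optionally `strain` and `phase`,
#'   plus the seven numeric behavior columns `attacks`, `chases`, `flights`,
#'   `uprights`, `locomotion_cm`, `exploration_frac`, `hiding_frac`.
#' @return The validated data frame (class `behavior_matrix` prepended).
#' @export
behavior_matrix <- function(df) {
  df <- as.data.frame(df)
  miss <- setdiff(c("mouse_id", "pair_id", BEHAVIOR_COLS), names(df))
  if (length(miss))
    stop("behavior matrix is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$mouse_id))
    stop("each mouse must appear exactly once")
  sizes <- table(df$pair_id)
  if (any(sizes != 2L))
    stop("pair ids must partition mice into pairs; offending: ",
         paste(names(sizes)[sizes != 2L], collapse = ", "))
  for (b in BEHAVIOR_COLS)
    if (!is.numeric(df[[b]])) stop("behavior column '", b, "' must be numeric")
  class(df) <- unique(c("behavior_matrix", class(df)))
  df
}

#' Read / write a behavior matrix as tidy long CSV
#'
#' The on-disk format is long: one row per mouse x behavior with columns
#' `mouse_id`, `pair_id`, `strain`, `phase`, `behavior`, `value`. This is
#' also the shape of a CSV export of a typical scoring spreadsheet (one
#' measure per sheet, flattened to rows).
#'
#' @param mat A [behavior_matrix()].
#' @param path CSV path.
#' @return `read_behavior_matrix()` a [behavior_matrix()];
#'   `write_behavior_matrix()` `path`, invisibly.
#' @export
write_behavior_matrix <- function(mat, path) {
  mat <- behavior_matrix(mat)
  strain <- if ("strain" %in% names(mat)) mat$strain else NA
  phase <- if ("phase" %in% names(mat)) mat$phase else NA
  long <- do.call(rbind, lapply(BEHAVIOR_COLS, function(b)
    data.frame(mouse_id = mat$mouse_id, pair_id = mat$pair_id,
               strain = strain, phase = phase, behavior = b,
               value = mat[[b]], stringsAsFactors = FALSE)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_matrix
#' @export
read_behavior_matrix <- function(path) {
  if (!file.exists(path)) stop("behavior matrix not found: ", path)
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mouse_id", "pair_id", "behavior", "value")
  miss <- setdiff(need, names(long))
  if (length(miss))
    stop("behavior matrix CSV is missing columns: ",
         paste(miss, collapse = ", "))
  ids <- unique(long$mouse_id)
  wide <- data.frame(mouse_id = ids, stringsAsFactors = FALSE)
  first <- long[!duplicated(long$mouse_id), ]
  wide$pair_id <- first$pair_id[match(ids, first$mouse_id)]
  for (extra in intersect(c("strain", "phase"), names(long)))
    wide[[extra]] <- first[[extra]][match(ids, first$mouse_id)]
  for (b in BEHAVIOR_COLS) {
    sub <- long[long$behavior == b, ]
    wide[[b]] <- sub$value[match(ids, sub$mouse_id)]
  }
  behavior_matrix(wide)
}

#' Z-score behaviors across the pooled cohort
#'
#' Each behavior column is centered and scaled across ALL mice (all strains
#' pooled), so strains share one normalization. Default uses the sample
#' (n - 1) standard deviation; `sd_type = "population"` divides by the
#' population (n) SD instead.
#'
#' @param mat A [behavior_matrix()].
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return Numeric mice x behaviors matrix of z-scores, rownames `mouse_id`.
#' @export
zscore_behaviors <- function(mat, sd_type = c("sample", "population")) {
  mat <- behavior_matrix(mat)
  sd_type <- match.arg(sd_type)
  if (nrow(mat) < 2L) stop("need at least 2 mice to z-score")
  m <- as.matrix(mat[, BEHAVIOR_COLS])
  rownames(m) <- mat$mouse_id
  for (b in BEHAVIOR_COLS) {
    v <- m[, b]
    if (anyNA(v)) stop("behavior '", b, "' has missing values")
    s <- stats::sd(v)
    if (sd_type == "population") s <- s * sqrt((length(v) - 1) / length(v))
    if (!is.finite(s) || s == 0)
      stop("behavior '", b, "' has zero variance across the cohort; ",
           "z-scores are undefined")
    m[, b] <- (v - mean(v)) / s
  }
  m
}

#' PCA of the z-scored behavior matrix
#'
#' Eigen-decomposition of the covariance of the standardized behaviors
#' (via [stats::prcomp()]); components are ordered by explained variance.
#' Component signs are fixed deterministically: PC1 and PC2 are oriented so
#' the attack loading is positive, hence a higher PC1 score means a more
#' aggressive/explorative animal and dominance is "higher PC1".
#'
#' @param z Standardized mice x behaviors matrix from [zscore_behaviors()]
#'   (no missing cells).
#' @return An object of class `dominance_result`: list with `loadings`
#'   (behaviors x components), `variance_frac` (fractions of total variance,
#'   non-increasing, summing to 1), `scores` (mice x components, rownames
#'   `mouse_id`) and `sdev`.
#' @export
dominance_pca <- function(z) {
  z <- as.matrix(z)
  if (anyNA(z)) stop("standardized matrix must not contain missing cells")
  if (nrow(z) < 2L) stop("need at least 2 mice")
  p <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  # orient on the attack loading when present, else on the first variable
  ref <- if ("attacks" %in% rownames(p$rotation)) "attacks" else 1L
  for (k in seq_len(min(2L, ncol(p$rotation)))) {
    a <- p$rotation[ref, k]
    if (is.finite(a) && a < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  structure(list(loadings = p$rotation,
                 variance_frac = p$sdev^2 / sum(p$sdev^2),
                 scores = p$x, sdev = p$sdev),
            class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  cat(sprintf("<dominance_result> %d mice, PC1 %.1f%% / PC2 %.1f%% variance\n",
              nrow(x$scores), 100 * x$variance_frac[1],
              100 * x$variance_frac[2]))
  invisible(x)
}

#' Assign dominant / subordinate labels from PC1 scores
#'
#' The pair member with the higher PC1 score is dominant; an exact tie flags
#' the pair as tied (no labels). The reported PC1 difference is dominant
#' minus subordinate, hence non-negative.
#'
#' @param result A [dominance_pca()] result.
#' @param pairs Data frame mapping `mouse_id` to `pair_id`.
#' @return Data frame `pair_id`, `dominant`, `subordinate`, `pc1_diff`,
#'   `tied`.
#' @export
assign_ranks <- function(result, pairs) {
  stopifnot(inherits(result, "dominance_result"),
            all(c("mouse_id", "pair_id") %in% names(pairs)))
  pc1 <- result$scores[, 1]
  out <- list()
  for (p in unique(pairs$pair_id)) {
    members <- as.character(pairs$mouse_id[pairs$pair_id == p])
    if (length(members) != 2L)
      stop("pair '", p, "' does not have exactly 2 members")
    if (!all(members %in% names(pc1)))
      stop("pair '", p, "': missing PC1 score for ",
           paste(setdiff(members, names(pc1)), collapse = ", "))
    s <- pc1[members]
    if (s[1] == s[2]) {
      out[[length(out) + 1L]] <- data.frame(
        pair_id = p, dominant = NA_character_, subordinate = NA_character_,
        pc1_diff = 0, tied = TRUE, stringsAsFactors = FALSE)
    } else {
      dom <- members[which.max(s)]
      sub <- setdiff(members, dom)
      out[[length(out) + 1L]] <- data.frame(
        pair_id = p, dominant = dom, subordinate = sub,
        pc1_diff = unname(s[dom] - s[sub]), tied = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# all perfect matchings of 1..n (n even), as list of 2-column matrices
enumerate_matchings <- function(n) {
  if (n == 0L) return(list(matrix(integer(0), 0, 2)))
  recurse <- function(rest) {
    if (!length(rest)) return(list(matrix(integer(0), 0, 2)))
    a <- rest[1]
    out <- list()
    for (b in rest[-1]) {
      subrest <- setdiff(rest, c(a, b))
      for (m in recurse(subrest))
        out[[length(out) + 1L]] <- rbind(c(a, b), m)
    }
    out
  }
  recurse(seq_len(n))
}

n_matchings <- function(n) prod(seq(n - 1, 1, by = -2))

#' Cohort re-pairing permutation test
#'
#' Tests whether the observed within-pair behavioral asymmetry exceeds what
#' random pairings of the same cohort produce. The statistic is the mean over
#' true pairs of the absolute within-pair difference; the null re-draws a
#' uniformly random perfect matching of the cohort into artificial pairs and
#' recomputes it. The p-value is the fraction of null draws at least as large
#' as the observed statistic (so identical values give p = 1, and p is never
#' 0 under exhaustive enumeration, which always includes matchings tying the
#' observed statistic). No add-one smoothing is applied to sampled p-values.
#'
#' When the number of distinct perfect matchings `(n-1)!!` is at most 10,005
#' (cohorts of up to 10 mice) the null is enumerated exhaustively instead of
#' sampled; `exact = FALSE` forces sampling.
#'
#' @param values Numeric vector, one value per mouse, names = mouse ids.
#' @param pairs Vector of pair ids parallel to `values` (each id twice).
#' @param n_perm Number of sampled permutations (default 10000; ignored under
#'   exhaustive enumeration).
#' @param seed Optional integer seed for the sampled null.
#' @param behavior Optional behavior name recorded in the result.
#' @param exact `NULL` (auto), `TRUE` or `FALSE`.
#' @return An object of class `permutation_result`: list with `behavior`,
#'   `observed`, `null` (numeric vector), `p_value`, `n_permutations`,
#'   `seed` and `method` (`"exhaustive"` or `"sampled"`).
#' @export
repairing_permutation_test <- function(values, pairs, n_perm = 10000,
                                       seed = NULL, behavior = NA_character_,
                                       exact = NULL) {
  n <- length(values)
  if (n %% 2L != 0L || n < 4L)
    stop("cohort size must be even and at least 4, got ", n)
  if (length(pairs) != n)
    stop("pairs must be parallel to values")
  sizes <- table(pairs)
  if (any(sizes != 2L))
    stop("each pair id must appear exactly twice")
  stopifnot(n_perm >= 1)
  stat <- function(idx_mat) {
    mean(abs(values[idx_mat[, 1]] - values[idx_mat[, 2]]))
  }
  true_mat <- do.call(rbind, lapply(unique(pairs), function(p)
    which(pairs == p)))
  observed <- stat(true_mat)
  use_exact <- if (is.null(exact)) n_matchings(n) <= 10005 else isTRUE(exact)
  if (use_exact) {
    null <- vapply(enumerate_matchings(n), stat, 0)
    method <- "exhaustive"
  } else {
    if (!is.null(seed)) set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i) {
      ord <- sample.int(n)
      stat(matrix(ord, ncol = 2, byrow = TRUE))
    }, 0)
    method <- "sampled"
  }
  structure(list(behavior = behavior, observed = observed, null = null,
                 p_value = mean(null >= observed - 1e-12),
                 n_permutations = length(null),
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 method = method),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("<permutation_result> %s: observed |diff| = %.4g, ",
                     "p = %.4g (%s, %d permutations)\n"),
              ifelse(is.na(x$behavior), "statistic", x$behavior),
              x$observed, x$p_value, x$method, x$n_permutations))
  invisible(x)
}

#' Pairwise behavior correlations with a significance mask
#'
#' Correlation matrix among the behavior columns (default Pearson; Spearman
#' selectable), with a mask of cells whose test p-value is below `alpha`.
#' No multiple-testing correction is applied by default; the adjustment
#' method used is recorded in the result metadata. Constant columns yield
#' undefined correlations: their cells are `NA` and the column is flagged.
#'
#' @param mat A [behavior_matrix()] or plain numeric matrix/data frame of
#'   variables in columns (>= 3 rows).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param alpha Significance level for the mask (default 0.05).
#' @param adjust A [stats::p.adjust()] method applied across the distinct
#'   variable pairs (default `"none"`).
#' @return An object of class `behavior_correlations`: list with `r`, `p`,
#'   `significant` (logical mask), `method`, `alpha`, `adjust`, `n` and
#'   `constant` (flagged constant columns).
#' @export
behavior_correlations <- function(mat, method = c("pearson", "spearman"),
                                  alpha = 0.05, adjust = "none") {
  method <- match.arg(method)
  mat_df <- as.data.frame(mat)
  m <- if (inherits(mat, "behavior_matrix")) {
    as.matrix(mat_df[, BEHAVIOR_COLS])
  } else {
    # keep every numeric column; id columns and the like drop out
    num <- vapply(mat_df, is.numeric, TRUE)
    if (!any(num)) stop("correlation input has no numeric columns")
    as.matrix(mat_df[, num, drop = FALSE])
  }
  if (nrow(m) < 3L) stop("need at least 3 mice for correlations")
  vars <- colnames(m)
  k <- length(vars)
  const <- vars[apply(m, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)]
  r <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  p <- r
  diag(r) <- ifelse(vars %in% const, NA_real_, 1)
  diag(p) <- ifelse(vars %in% const, NA_real_, 0)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (vars[i] %in% const || vars[j] %in% const) next
    ct <- suppressWarnings(
      stats::cor.test(m[, i], m[, j], method = method, exact = FALSE))
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  up <- upper.tri(p)
  p[up] <- stats::p.adjust(p[up], method = adjust)
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  structure(list(r = r, p = p,
                 significant = !is.na(p) & p < alpha,
                 method = method, alpha = alpha, adjust = adjust,
                 n = nrow(m), constant = const),
            class = "behavior_correlations")
}

#' @export
print.behavior_correlations <- function(x, ...) {
  cat(sprintf(paste0("<behavior_correlations> %d x %d (%s, n = %d), ",
                     "%d significant at alpha = %g\n"),
              nrow(x$r), ncol(x$r), x$method, x$n,
              sum(x$significant[upper.tri(x$significant)], na.rm = TRUE),
              x$alpha))
  if (length(x$constant))
    cat("  constant (undefined) columns:",
        paste(x$constant, collapse = ", "), "\n")
  invisible(x)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Thin delegation to [stats::wilcox.test()] with one convention added: when
#' every paired difference is zero the test is undefined in base R, and this
#' wrapper returns statistic 0 with p = 1.
#'
#' @param x,y Paired numeric vectors.
#' @param ... Passed to [stats::wilcox.test()].
#' @return List with `statistic` and `p_value` (plus the underlying `htest`
#'   when defined).
#' @export
paired_wilcoxon <- function(x, y, ...) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  if (all(x == y))
    return(list(statistic = 0, p_value = 1, htest = NULL))
  ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, ...))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, htest = ht)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' The omnibus test delegates to [stats::kruskal.test()]. Dunn's pairwise
#' comparisons use the standard rank-sum z statistic with tie correction,
#' two-sided normal p-values and Bonferroni adjustment by default.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping factor/vector parallel to `values`.
#' @param p_adjust Adjustment method for the pairwise p-values
#'   (default `"bonferroni"`).
#' @return List with `kw` (the `htest`), `H`, `p_value` and `dunn` (data
#'   frame `group1`, `group2`, `z`, `p`, `p_adj`).
#' @export
kruskal_dunn <- function(values, groups, p_adjust = "bonferroni") {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 values")
  if (length(unique(values)) == 1L) {
    # degenerate case: no rank information at all -> H = 0, p = 1
    lv <- levels(groups)
    cmb <- utils::combn(lv, 2)
    dunn <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ], z = 0,
                       p = 1, p_adj = 1, stringsAsFactors = FALSE)
    return(list(kw = NULL, H = 0, p_value = 1, dunn = dunn))
  }
  kw <- stats::kruskal.test(values, groups)
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  res <- list()
  for (i in seq_len(length(lv) - 1)) for (j in (i + 1):length(lv)) {
    gi <- groups == lv[i]; gj <- groups == lv[j]
    ri <- mean(rk[gi]); rj <- mean(rk[gj])
    sigma <- sqrt((N * (N + 1) / 12 - tie_corr) *
                  (1 / sum(gi) + 1 / sum(gj)))
    z <- (ri - rj) / sigma
    res[[length(res) + 1L]] <- data.frame(
      group1 = lv[i], group2 = lv[j], z = z,
      p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }
  dunn <- do.call(rbind, res)
  dunn$p_adj <- stats::p.adjust(dunn$p, method = p_adjust)
  list(kw = kw, H = unname(kw$statistic), p_value = kw$p.value, dunn = dunn)
}

# (a - b) / (a + b), the shared form of the validation indices
index_ratio <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(a < 0 | b < 0)) stop("times must be non-negative")
  out <- (a - b) / (a + b)
  undef <- a + b == 0
  if (any(undef)) {
    warning("index undefined where both times are zero; returning NA")
    out[undef] <- NA_real_
  }
  out
}

#' Dye-treatment validation indices
#'
#' `anxiety_index()` is the open-field measure
#' `(T_center - T_corners) / (T_center + T_corners)`; `preference_index()`
#' the odor-preference measure `(T_dye - T_saline) / (T_dye + T_saline)`.
#' Both lie in `[-1, 1]`; a both-zero input is undefined and returns `NA`
#' with a warning.
#'
#' @param t_center,t_corners,t_dye,t_saline Non-negative times in seconds
#'   (vectorized).
#' @return Numeric index in `[-1, 1]`.
#' @export
anxiety_index <- function(t_center, t_corners) index_ratio(t_center, t_corners)

#' @rdname anxiety_index
#' @export
preference_index <- function(t_dye, t_saline) index_ratio(t_dye, t_saline)
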