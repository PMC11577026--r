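#' End-to-end analysis pipeline
#'
#' `run_pipeline()` chains the stages — cohort input (synthetic by default),
#' trajectory metrics, behavior matrix, z-scoring, PCA, rank assignment,
#' re-pairing permutation tests, behavior correlations, flight-aligned
#' kinematics and urine-mark quantification — deterministically under one
#' seed, and optionally writes tidy CSV outputs plus a JSON metadata sidecar.
#'
#' @name pipeline
NULL

PIPELINE_DEFAULTS <- list(
  seed = 1L,
  n_pairs = 10L,
  divergence = 1,
  session_min = 120,
  frame_rate_hz = 45,
  layout = NULL,            # path to a layout YAML; NULL = default layout
  late = "last20",
  anchor = "middle_back",
  min_dwell_s = 1,
  proximity_cm = 10,
  conf_threshold = 0.6,
  n_perm = 1000L,
  alpha = 0.05,
  correlation_method = "pearson",
  mark_px_per_cm = 2,
  kinematics = TRUE,
  marking = TRUE,
  out_dir = NULL)

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys and checks types/ranges before any
#' computation; every defaulted value is reported via `message()` when
#' `verbose`.
#'
#' @param config Named list of overrides (possibly empty), or a path to a
#'   YAML file holding one.
#' @param verbose Report defaulted values (default `FALSE`).
#' @return The completed configuration list.
#' @export
pipeline_config <- function(config = list(), verbose = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(PIPELINE_DEFAULTS))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, config, keep.null = TRUE)
  defaulted <- setdiff(names(PIPELINE_DEFAULTS), names(config))
  if (verbose && length(defaulted))
    message("defaulted config values: ", paste(defaulted, collapse = ", "))
  stopifnot(cfg$n_pairs >= 1, cfg$divergence >= 0, cfg$divergence <= 1,
            cfg$n_perm >= 1, cfg$alpha > 0, cfg$alpha < 1,
            cfg$min_dwell_s >= 0, cfg$proximity_cm > 0,
            cfg$conf_threshold >= 0, cfg$conf_threshold <= 1)
  if (!is.null(cfg$layout) && !file.exists(cfg$layout))
    stop("layout file not found: ", cfg$layout)
  cfg$late <- match.arg(cfg$late, c("last20", "100_110"))
  cfg$correlation_method <- match.arg(cfg$correlation_method,
                                      c("pearson", "spearman"))
  cfg
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' @param config A configuration list or YAML path (see [pipeline_config()]);
#'   keys: `seed`, `n_pairs`, `divergence`, `session_min`, `frame_rate_hz`,
#'   `layout`, `late`, `anchor`, `min_dwell_s`, `proximity_cm`,
#'   `conf_threshold`, `n_perm`, `alpha`, `correlation_method`,
#'   `mark_px_per_cm`, `kinematics`, `marking`, `out_dir`.
#' @param verbose Report progress and defaulted config values.
#' @return A list with `config`, `cohort` (pair table, events, truth),
#'   `behavior_matrix`, `zscores`, `pca` (a `dominance_result`), `ranks`,
#'   `permutation` (one `permutation_result` per behavior), `correlations`,
#'   `kinematics` (pooled late-phase `flight_kinematics`, or `NULL`),
#'   `marking` (per-mouse marked percents + correlation with behaviors, or
#'   `NULL`) and `recovery` (fraction of pairs whose planted dominant was
#'   recovered).
#' @export
run_pipeline <- function(config = list(), verbose = FALSE) {
  cfg <- pipeline_config(config, verbose = verbose)
  layout <- if (is.null(cfg$layout)) {
    default_layout(frame_rate_hz = cfg$frame_rate_hz)
  } else read_layout(cfg$layout)
  spec <- cohort_spec(n_pairs = cfg$n_pairs, session_min = cfg$session_min,
                      frame_rate_hz = cfg$frame_rate_hz,
                      divergence = cfg$divergence, seed = cfg$seed)
  if (verbose) message("simulating cohort of ", cfg$n_pairs, " pairs")
  keep <- isTRUE(cfg$kinematics)
  cohort <- simulate_cohort(spec, compute_metrics = TRUE, keep_tracks = keep)
  bm <- cohort$behavior_matrix
  z <- zscore_behaviors(bm)
  pca <- dominance_pca(z)
  ranks <- assign_ranks(pca, cohort$pair_table)
  truth_dom <- vapply(cohort$truth, `[[`, "", "dominant")
  recovery <- mean(ranks$dominant[match(names(truth_dom), ranks$pair_id)] ==
                   truth_dom, na.rm = FALSE)
  perm <- list()
  for (b in BEHAVIOR_COLS) {
    vals <- stats::setNames(bm[[b]], bm$mouse_id)
    perm[[b]] <- repairing_permutation_test(
      vals, bm$pair_id, n_perm = cfg$n_perm,
      seed = cfg$seed + match(b, BEHAVIOR_COLS), behavior = b)
  }
  corr <- behavior_correlations(bm, method = cfg$correlation_method,
                                alpha = cfg$alpha)
  kin <- NULL
  if (isTRUE(cfg$kinematics)) {
    if (verbose) message("flight-aligned kinematics (late phase)")
    kin <- pooled_kinematics(cohort, layout, cfg)
    cohort$pairs <- NULL  # tracks no longer needed
  }
  mk <- NULL
  if (isTRUE(cfg$marking)) {
    if (verbose) message("urine-mark rendering and segmentation")
    mk <- marking_stage(cohort, bm, cfg)
  }
  result <- list(config = cfg,
                 cohort = list(pair_table = cohort$pair_table,
                               events = cohort$events,
                               truth = cohort$truth),
                 behavior_matrix = bm, zscores = z, pca = pca,
                 ranks = ranks, permutation = perm, correlations = corr,
                 kinematics = kin, marking = mk, recovery = recovery)
  if (!is.null(cfg$out_dir)) write_results(result, cfg$out_dir)
  result
}

# pool flight windows of the late phase across all pairs: detect centers per
# pair on its own frame grid, then average all windows frame by frame
pooled_kinematics <- function(cohort, layout, cfg) {
  phases <- phase_windows(cohort$spec$session_min, late = cfg$late)
  win <- phases$late
  speed_all <- c(); dist_all <- c()
  per_pair <- list()
  for (pid in names(cohort$pairs)) {
    pr <- cohort$pairs[[pid]]
    tr <- lapply(pr$tracks, crop_track, window = win)
    cl <- lapply(tr, clean_track, conf_threshold = cfg$conf_threshold)
    sp <- lapply(cl, speed_series, anchor = cfg$anchor)
    dist <- distance_series(cl[[1]], cl[[2]], cfg$anchor)
    fl <- pr$events[pr$events$behavior == "flight" &
                    pr$events$onset_s >= win[1] &
                    pr$events$onset_s < win[2], , drop = FALSE]
    if (!nrow(fl)) next
    fl$onset_s <- fl$onset_s - win[1]
    per_pair[[pid]] <- flight_aligned_kinematics(
      fl, sp, dist, frame_rate_hz = cohort$spec$frame_rate_hz)
  }
  if (!length(per_pair)) return(NULL)
  # weighted frame-wise pooling over pairs by contributing flight counts
  nf <- length(per_pair[[1]]$time_s)
  num_s <- numeric(nf); num_d <- numeric(nf); den <- numeric(nf)
  for (k in per_pair) {
    ok <- k$n > 0
    num_s[ok] <- num_s[ok] + k$speed_mean[ok] * k$n[ok]
    num_d[ok] <- num_d[ok] + k$dist_mean[ok] * k$n[ok]
    den[ok] <- den[ok] + k$n[ok]
  }
  list(time_s = per_pair[[1]]$time_s,
       speed_mean = ifelse(den > 0, num_s / den, NA_real_),
       dist_mean = ifelse(den > 0, num_d / den, NA_real_),
       n = den, per_pair = per_pair)
}

# render, segment and quantify one floor image per pair; dominant carries
# fluorescein by protocol convention
marking_stage <- function(cohort, bm, cfg) {
  rows <- list()
  for (pid in names(cohort$truth)) {
    tr <- cohort$truth[[pid]]
    dom <- tr$dominant
    sub <- setdiff(cohort$pair_table$mouse_id[
      cohort$pair_table$pair_id == pid], dom)
    rmi <- render_mark_image(c(tr$mark_pct[dom], tr$mark_pct[sub]),
                             px_per_cm = cfg$mark_px_per_cm,
                             seed = cfg$seed * 100 +
                               match(pid, names(cohort$truth)))
    labs <- segment_dyes(rmi$image)
    q <- percent_marked_area(labs, rmi$image$mask)
    rows[[pid]] <- data.frame(
      mouse_id = c(dom, sub),
      dye = c("fluorescein", "erythrosin"),
      marked_pct = as.numeric(q$percent[c("fluorescein", "erythrosin")]),
      truth_pct = 100 * c(sum(rmi$truth == 1L), sum(rmi$truth == 2L)) /
        length(rmi$truth),
      pair_id = pid, stringsAsFactors = FALSE)
  }
  marking <- do.call(rbind, rows)
  rownames(marking) <- NULL
  corr <- marking_vs_behavior(marking, bm,
                              method = cfg$correlation_method,
                              alpha = cfg$alpha)
  list(table = marking, correlations = corr)
}

#' Write pipeline results as tidy CSV plus a JSON metadata sidecar
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_behavior_matrix(result$behavior_matrix,
                        file.path(out_dir, "behavior_matrix.csv"))
  utils::write.csv(result$ranks, file.path(out_dir, "ranks.csv"),
                   row.names = FALSE)
  scores <- data.frame(mouse_id = rownames(result$pca$scores),
                       pc1 = result$pca$scores[, 1],
                       pc2 = result$pca$scores[, 2])
  utils::write.csv(scores, file.path(out_dir, "pca_scores.csv"),
                   row.names = FALSE)
  load_df <- as.data.frame(result$pca$loadings[, 1:2])
  load_df <- cbind(behavior = rownames(load_df), load_df)
  utils::write.csv(load_df, file.path(out_dir, "pca_loadings.csv"),
                   row.names = FALSE)
  perm_df <- do.call(rbind, lapply(result$permutation, function(p)
    data.frame(behavior = p$behavior, observed = p$observed,
               p_value = p$p_value, n_permutations = p$n_permutations,
               method = p$method)))
  utils::write.csv(perm_df, file.path(out_dir, "permutation_tests.csv"),
                   row.names = FALSE)
  if (!is.null(result$marking))
    utils::write.csv(result$marking$table,
                     file.path(out_dir, "marking.csv"), row.names = FALSE)
  if (!is.null(result$kinematics))
    utils::write.csv(data.frame(time_s = result$kinematics$time_s,
                                speed_mean = result$kinematics$speed_mean,
                                dist_mean = result$kinematics$dist_mean,
                                n = result$kinematics$n),
                     file.path(out_dir, "kinematics.csv"), row.names = FALSE)
  meta <- list(
    package = "territr",
    version = as.character(utils::packageVersion("territr")),
    r_version = R.version.string,
    seed = result$config$seed,
    config = result$config[setdiff(names(result$config), "out_dir")],
    conventions = list(
      pc_sign = "PC1/PC2 oriented so the attack loading is positive",
      p_value = "fraction of null >= observed; no add-one smoothing",
      dwell_filter = "bouts < min_dwell_s discarded per ROI before summation",
      sd = "z-scores use the sample (n-1) standard deviation"))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
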