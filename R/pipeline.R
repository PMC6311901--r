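#' Run the full feature-screening pipeline on a cohort
#'
#' End-to-end driver: (optional) near-duplicate removal, feature
#' extraction, mean imputation, min-max scaling, redundancy pruning, KS
#' importance ranking, C sweep, and C selection — the order used
#' throughout this package (Pearson correlations are invariant to the
#' affine scaling, so pruning before or after scaling is equivalent).
#' Feature columns observed in no transcript are dropped (with a message)
#' before imputation.
#'
#' @param ts Named list of [transcript] objects, or a cohort from
#'   [generate_cohort()] (whose labels/repeats/planted injections are then
#'   used automatically).
#' @param labels Labels (ignored when `ts` is a cohort).
#' @param tables Reference tables from [build_reference_tables()].
#' @param repeats Repeat annotation (ignored when `ts` is a cohort).
#' @param dedup_threshold Similarity threshold in percent; `NULL` skips
#'   duplicate removal (e.g. for synthetic cohorts built without shared
#'   sequence).
#' @param max_span Stem-profile pairing span (see [stem_profile()]).
#' @param prune_threshold Absolute-correlation threshold of
#'   [prune_redundant()].
#' @param grid,split_seed,cv_folds,epsilon,select_on Passed to [sweep_C()]
#'   and [select_C()].
#' @param verbose Progress messages.
#' @return List with `features` (raw [feature_matrix]), `scaled`,
#'   `pruned`, `prune_log`, `ks` (ranking), `sweep`, `selection`,
#'   `report`, and `manifest` (seeds/configuration; serialize with
#'   [jsonlite::toJSON()]).
#' @export
run_pipeline <- function(ts, labels = NULL, tables = NULL, repeats = NULL,
                         dedup_threshold = NULL, max_span = 100L,
                         prune_threshold = 0.8,
                         grid = seq(0.01, 1, by = 0.01), split_seed = 1L,
                         cv_folds = 5L, epsilon = 0.005,
                         select_on = "test", verbose = FALSE) {
  cohort <- NULL
  if (is.list(ts) && !is.null(ts$transcripts) && !is.null(ts$labels)) {
    cohort <- ts
    labels <- cohort$labels
    if (is.null(repeats)) repeats <- cohort$repeats
    ts <- cohort$transcripts
  }
  if (!is.null(dedup_threshold)) {
    ts <- deduplicate(ts, threshold = dedup_threshold)
    labels <- labels[vapply(ts, `[[`, "", "id")]
  }
  if (verbose) message("extracting features from ", length(ts), " transcripts")
  m <- extract_features(ts, tables = tables, repeats = repeats,
                        max_span = max_span, labels = labels,
                        verbose = verbose)
  if (!is.null(cohort)) m <- apply_planted_injections(m, cohort)
  all_na <- colnames(m$X)[colSums(!is.na(m$X)) == 0]
  if (length(all_na)) {
    if (verbose) message("dropping all-missing feature(s): ",
                         paste(all_na, collapse = ", "))
    keep <- setdiff(colnames(m$X), all_na)
    m <- feature_matrix(m$X[, keep, drop = FALSE], y = m$y, ids = m$ids)
  }
  scaled <- minmax_scale(impute_mean(m))
  pr <- prune_redundant(scaled, threshold = prune_threshold)
  ks <- ks_rank(pr$matrix)
  sw <- sweep_C(pr$matrix, grid = grid, split_seed = split_seed,
                cv_folds = cv_folds)
  sel <- select_C(sw, epsilon = epsilon, select_on = select_on)
  rep_df <- suppressWarnings(report_features(sel$model))
  manifest <- list(
    package_version = as.character(utils::packageVersion("ribolnc")),
    n_transcripts = length(ts),
    n_features_extracted = ncol(m$X),
    n_features_pruned = ncol(pr$matrix$X),
    cohort_seed = if (!is.null(cohort)) cohort$config$seed else NULL,
    split_seed = split_seed,
    max_span = max_span,
    prune_threshold = prune_threshold,
    grid = c(min(grid), max(grid), length(grid)),
    epsilon = epsilon,
    select_on = select_on,
    chosen_C = sel$chosen_C,
    accuracy = sel$accuracy,
    n_selected = sel$n_selected)
  list(features = m, scaled = scaled, pruned = pr$matrix, prune_log = pr$log,
       ks = ks, sweep = sw, selection = sel, report = rep_df,
       manifest = manifest)
}

#' Planted-feature recovery experiment
#'
#' Repeats, over seeded replicates: simulate a feature-space cohort with
#' planted signed effects ([simulate_feature_matrix()]), run the selection
#' chain (impute, scale, prune, sweep, select), and score whether the
#' selected model recovers every planted feature with the correct
#' coefficient sign and how many unplanted features enter the model.
#'
#' @param n_replicates Number of replicates.
#' @param seed Base seed (replicate r uses a derived stream).
#' @param n_per_class,n_features,delta,noise_sd As in
#'   [simulate_feature_matrix()].
#' @param grid C grid for the sweep (default coarse 0.01..1 step 0.01).
#' @param epsilon Accuracy slack of [select_C()].
#' @return `data.frame` with one row per replicate: `replicate`,
#'   `recovered` (all planted, correct signs), `n_false_pos`, `chosen_C`,
#'   `accuracy`.
#' @export
recovery_experiment <- function(n_replicates = 20L, seed = 1L,
                                n_per_class = 400L, n_features = 24L,
                                delta = 0.1, noise_sd = 0.05,
                                grid = seq(0.01, 1, by = 0.01),
                                epsilon = 0.005) {
  rows <- lapply(seq_len(n_replicates), function(r) {
    rs <- derive_seed(seed, paste0("rep", r))
    m <- simulate_feature_matrix(n_per_class = n_per_class,
                                 n_features = n_features,
                                 delta = delta, noise_sd = noise_sd,
                                 seed = rs)
    truth <- attr(m, "truth")
    scaled <- minmax_scale(impute_mean(m))
    pruned <- prune_redundant(scaled)$matrix
    sw <- sweep_C(pruned, grid = grid,
                  split_seed = derive_seed(rs, "split"))
    sel <- select_C(sw, epsilon = epsilon)
    w <- sel$model$w
    signs <- ifelse(w > 0, "+", ifelse(w < 0, "-", "0"))
    ok <- all(truth$feature %in% names(w)) &&
      all(signs[truth$feature] == truth$sign)
    n_fp <- sum(w[setdiff(names(w), truth$feature)] != 0)
    data.frame(replicate = r, recovered = ok, n_false_pos = n_fp,
               chosen_C = sel$chosen_C, accuracy = sel$accuracy)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
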