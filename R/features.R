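#' Feature matrix container
#'
#' Transcripts-by-features numeric matrix with ids, optional 0/1 labels
#' (0 = ribosome-free, 1 = ribosome-associated), and a missingness mask
#' recording which entries were observed before imputation.
#'
#' @param X Numeric matrix (rows = transcripts) with column names.
#' @param y Optional 0/1 label vector (one per row).
#' @param ids Transcript ids (default rownames of `X`).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(X, y = NULL, ids = rownames(X)) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("feature matrix needs column names")
  if (anyDuplicated(colnames(X))) {
    stop("duplicate feature names: ",
         paste(unique(colnames(X)[duplicated(colnames(X))]), collapse = ", "))
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  if (!is.null(y)) {
    y <- as.integer(y)
    if (length(y) != nrow(X) || !all(y %in% c(0L, 1L))) {
      stop("labels must be one 0/1 value per transcript")
    }
  }
  rownames(X) <- ids
  structure(list(ids = as.character(ids), feature_names = colnames(X),
                 X = X, y = y, mask = is.na(X)),
            class = "feature_matrix")
}

#' @exportS3Method base::print
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$X), " transcripts x ", ncol(x$X), " features",
      if (!is.null(x$y)) paste0(" (", sum(x$y == 1), " ribo / ", sum(x$y == 0),
                                " noribo)"),
      "; ", sum(is.na(x$X)), " missing\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$X)

#' Column-join per-module feature tables into a feature matrix
#'
#' Each table is a `data.frame` with an `id` column plus numeric feature
#' columns.  All tables must cover the same transcript ids; duplicate
#' feature names across tables are an error; a feature observed in no
#' transcript triggers a warning.  Missing values are preserved (see
#' [impute_mean()]).
#'
#' @param tables List of feature `data.frame`s (each with an `id` column).
#' @param labels Optional labels: named 0/1 vector, or `data.frame` with
#'   columns `id` and `label`.
#' @return A [feature_matrix].
#' @export
assemble <- function(tables, labels = NULL) {
  stopifnot(length(tables) >= 1)
  ids <- tables[[1]]$id
  for (tb in tables) {
    if (is.null(tb$id)) stop("every feature table needs an 'id' column")
    if (!setequal(tb$id, ids) || length(tb$id) != length(ids)) {
      stop("inconsistent transcript ids across feature tables: ",
           paste(head(c(setdiff(ids, tb$id), setdiff(tb$id, ids)), 5),
                 collapse = ", "))
    }
  }
  mats <- lapply(tables, function(tb) {
    tb <- tb[match(ids, tb$id), , drop = FALSE]
    as.matrix(tb[, setdiff(colnames(tb), "id"), drop = FALSE])
  })
  X <- do.call(cbind, mats)
  if (anyDuplicated(colnames(X))) {
    stop("duplicate feature name(s): ",
         paste(unique(colnames(X)[duplicated(colnames(X))]), collapse = ", "))
  }
  all_na <- colnames(X)[colSums(!is.na(X)) == 0]
  if (length(all_na)) {
    warning("feature(s) observed in no transcript: ",
            paste(all_na, collapse = ", "))
  }
  y <- NULL
  if (!is.null(labels)) {
    if (is.data.frame(labels)) labels <- setNames(labels$label, labels$id)
    if (!all(ids %in% names(labels))) {
      stop("labels missing for: ",
           paste(head(setdiff(ids, names(labels)), 5), collapse = ", "))
    }
    y <- as.integer(labels[ids])
  }
  feature_matrix(X, y = y, ids = as.character(ids))
}

#' Mean imputation of missing feature values
#'
#' Replaces each missing entry by the mean of the observed entries of its
#' column.  A column with no observed value is an error (drop it first).
#'
#' @param m A [feature_matrix].
#' @return The imputed [feature_matrix] (original mask retained).
#' @export
impute_mean <- function(m) {
  X <- m$X
  all_na <- colnames(X)[colSums(!is.na(X)) == 0]
  if (length(all_na)) {
    stop("cannot impute all-missing column(s): ", paste(all_na, collapse = ", "))
  }
  for (j in seq_len(ncol(X))) {
    na <- is.na(X[, j])
    if (any(na)) X[na, j] <- mean(X[!na, j])
  }
  out <- feature_matrix(X, y = m$y, ids = m$ids)
  out$mask <- m$mask
  out
}

#' Min-max scale features to [0, 1]
#'
#' Column-wise `(x - min) / (max - min)`; constant columns map to all 0.
#' Expects an imputed matrix.
#'
#' @param m A [feature_matrix].
#' @return The scaled [feature_matrix].
#' @export
minmax_scale <- function(m) {
  X <- m$X
  for (j in seq_len(ncol(X))) {
    rng <- range(X[, j], na.rm = TRUE)
    X[, j] <- if (rng[2] > rng[1]) (X[, j] - rng[1]) / (rng[2] - rng[1]) else 0
  }
  out <- feature_matrix(X, y = m$y, ids = m$ids)
  out$mask <- m$mask
  out
}

#' Prune highly correlated (redundant) features
#'
#' Iteratively removes features until no surviving pair has absolute
#' Pearson correlation above `threshold`: at each step the feature with
#' the most over-threshold partners is removed (ties: larger mean absolute
#' correlation with all other features, then later column order).  The
#' removal log records each removed feature and its trigger partners.
#'
#' @param m A [feature_matrix] (imputed; scaling does not change Pearson
#'   correlations).
#' @param threshold Absolute-correlation threshold (default 0.8).
#' @return List with `matrix` (pruned [feature_matrix]) and `log`
#'   (`data.frame`: `removed`, `n_partners`, `max_abs_r`, `partners`).
#' @export
prune_redundant <- function(m, threshold = 0.8) {
  X <- m$X
  log_rows <- list()
  repeat {
    r <- suppressWarnings(cor(X))
    r[is.na(r)] <- 0
    a <- abs(r); diag(a) <- 0
    over <- a > threshold
    if (!any(over)) break
    deg <- rowSums(over)
    cand <- which(deg == max(deg))
    if (length(cand) > 1) {
      mean_r <- rowMeans(a)[cand]
      cand <- cand[mean_r == max(mean_r)]
    }
    drop <- cand[length(cand)]                    # later column order
    partners <- colnames(X)[over[drop, ]]
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(removed = colnames(X)[drop], n_partners = deg[[drop]],
                 max_abs_r = max(a[drop, ]),
                 partners = paste(partners, collapse = ","),
                 stringsAsFactors = FALSE)
    X <- X[, -drop, drop = FALSE]
  }
  # post-condition asserted on every run
  r <- suppressWarnings(cor(X)); r[is.na(r)] <- 0; diag(r) <- 0
  stopifnot(all(abs(r) <= threshold))
  out <- feature_matrix(X, y = m$y, ids = m$ids)
  out$mask <- m$mask[, colnames(X), drop = FALSE]
  lg <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(removed = character(0), n_partners = integer(0),
               max_abs_r = numeric(0), partners = character(0))
  rownames(lg) <- NULL
  list(matrix = out, log = lg)
}

# Two-sample KS statistic D = sup |ECDF0 - ECDF1|.
ks_D <- function(x0, x1) {
  pts <- sort(unique(c(x0, x1)))
  e0 <- vapply(pts, function(v) mean(x0 <= v), 0)
  e1 <- vapply(pts, function(v) mean(x1 <= v), 0)
  max(abs(e0 - e1))
}

# Exact permutation p-value: enumerate every assignment of the pooled
# values into groups of the observed sizes; p = fraction with D >= D_obs.
ks_exact_p <- function(x0, x1) {
  pool <- c(x0, x1)
  n <- length(pool); n0 <- length(x0)
  d_obs <- ks_D(x0, x1)
  idx <- combn(n, n0)
  hits <- 0L
  for (k in seq_len(ncol(idx))) {
    d <- ks_D(pool[idx[, k]], pool[-idx[, k]])
    if (d >= d_obs - 1e-12) hits <- hits + 1L
  }
  hits / ncol(idx)
}

#' Rank features by Kolmogorov-Smirnov importance
#'
#' For every feature, the two-sample KS statistic `D` between the
#' class-0 and class-1 value distributions and its p-value: the exact
#' permutation p (full enumeration) when both groups have at most
#' `exact_max` samples, the asymptotic two-sided p otherwise.  Features
#' are ranked by importance `-log10(p)`, descending (ties by `D`).
#'
#' @param m A labeled [feature_matrix].
#' @param exact_max Largest group size for the exact permutation p
#'   (default 10).
#' @return `data.frame` with columns `feature`, `D`, `p`, `importance`,
#'   sorted by decreasing importance.
#' @export
ks_rank <- function(m, exact_max = 10L) {
  if (is.null(m$y)) stop("ks_rank() needs labels")
  x0_all <- m$X[m$y == 0, , drop = FALSE]
  x1_all <- m$X[m$y == 1, , drop = FALSE]
  if (nrow(x0_all) < 2 || nrow(x1_all) < 2) {
    stop("need at least 2 samples per class")
  }
  res <- lapply(colnames(m$X), function(f) {
    x0 <- x0_all[, f]; x1 <- x1_all[, f]
    x0 <- x0[!is.na(x0)]; x1 <- x1[!is.na(x1)]
    D <- ks_D(x0, x1)
    p <- if (length(x0) <= exact_max && length(x1) <= exact_max) {
      ks_exact_p(x0, x1)
    } else {
      suppressWarnings(ks.test(x0, x1, exact = FALSE))$p.value
    }
    p <- min(max(p, 1e-300), 1)
    data.frame(feature = f, D = D, p = p, importance = -log10(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$importance, -out$D, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Write / read a feature matrix as TSV
#'
#' One row per transcript: `id`, feature columns, and (when present) a
#' final `label` column.
#'
#' @param m A [feature_matrix].
#' @param path TSV path.
#' @return `read_feature_matrix()` returns a [feature_matrix].
#' @export
write_feature_matrix <- function(m, path) {
  df <- data.frame(id = m$ids, as.data.frame(m$X), check.names = FALSE)
  if (!is.null(m$y)) df$label <- m$y
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  y <- if ("label" %in% colnames(df)) df$label else NULL
  feats <- setdiff(colnames(df), c("id", "label"))
  feature_matrix(as.matrix(df[, feats, drop = FALSE]), y = y, ids = df$id)
}
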