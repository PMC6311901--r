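#' Fit an L1-regularized logistic regression at a fixed C
#'
#' Minimizes `||w||_1 + C * sum_i log(1 + exp(-y_i (X_i' w + c)))` with the
#' 0/1 labels mapped internally to -1/+1.  `C` is the inverse
#' regularization strength: larger C means a weaker penalty and more
#' nonzero coefficients.  The fit is delegated to a coordinate-descent
#' solver (glmnet) via the equivalence `lambda = 1 / (n * C)` with no
#' predictor standardization; the objective above is what the returned
#' model minimizes, and [l1_objective()] evaluates it directly.
#' Coefficients smaller than `10 * tol` in absolute value are reported as
#' exactly zero.  The fit is deterministic given `(X, y, C, tol)`.
#'
#' @param X Numeric matrix (imputed, scaled), one row per sample.
#' @param y 0/1 labels.
#' @param C Inverse regularization strength (> 0).
#' @param tol Solver convergence threshold.
#' @return An object of class `lr_model`: list with `w` (named
#'   coefficients), `c` (intercept), `C`, `tol`.
#' @export
fit_l1_lr <- function(X, y, C, tol = 1e-9) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("fit_l1_lr: labels contain a single class")
  n <- nrow(X)
  lam <- 1 / (n * C)
  fit <- glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                        alpha = 1, lambda = lam * c(64, 16, 4, 1),
                        standardize = FALSE, thresh = tol, maxit = 5e5)
  k <- length(fit$lambda)
  w <- as.numeric(fit$beta[, k])
  w[abs(w) < 10 * tol] <- 0
  names(w) <- colnames(X)
  structure(list(w = w, c = unname(fit$a0[k]), C = C, tol = tol),
            class = "lr_model")
}

#' @exportS3Method base::print
print.lr_model <- function(x, ...) {
  cat("<lr_model> C = ", x$C, ", ", sum(x$w != 0), "/", length(x$w),
      " nonzero coefficients, intercept ", round(x$c, 4), "\n", sep = "")
  invisible(x)
}

#' Evaluate the L1-logistic objective
#'
#' `||w||_1 + C * sum_i log(1 + exp(-y_i (X_i' w + c)))` with `y`
#' in -1/+1 (0/1 input is mapped).
#'
#' @param w Coefficient vector.
#' @param intercept Intercept `c`.
#' @param X Design matrix.
#' @param y 0/1 labels.
#' @param C Inverse regularization strength.
#' @return Objective value (scalar).
#' @export
l1_objective <- function(w, intercept, X, y, C) {
  yy <- 2 * as.numeric(y) - 1
  eta <- as.numeric(X %*% w + intercept)
  sum(abs(w)) + C * sum(log1p(exp(-yy * eta)))
}

#' @param object An `lr_model`.
#' @param newdata Feature matrix with the model's columns.
#' @param type `"prob"` for class-1 probabilities, `"class"` for 0/1 calls
#'   (probability >= 0.5).
#' @param ... Unused.
#' @rdname fit_l1_lr
#' @export
predict.lr_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- plogis(as.numeric(as.matrix(newdata) %*% object$w + object$c))
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Confusion counts and accuracy
#'
#' `confusion_counts()` tallies TP/TN/FP/FN of 0/1 predictions against 0/1
#' truth (positive class = 1, the ribosome-associated label);
#' `accuracy()` is `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param truth,pred 0/1 vectors of equal length.
#' @return `confusion_counts()`: list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred))
  list(TP = sum(truth == 1 & pred == 1), TN = sum(truth == 0 & pred == 0),
       FP = sum(truth == 0 & pred == 1), FN = sum(truth == 1 & pred == 0))
}

#' @param cc Confusion counts from [confusion_counts()].
#' @rdname confusion_counts
#' @export
accuracy <- function(cc) {
  total <- cc$TP + cc$TN + cc$FP + cc$FN
  if (total == 0) stop("accuracy undefined for empty test set")
  (cc$TP + cc$TN) / total
}

# Stratified split/fold helpers (seeded).
stratified_split <- function(y, test_frac, seed) {
  with_seed(seed, {
    test <- unlist(lapply(unique(y), function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1L, round(test_frac * length(idx))))
    }))
  })
  sort(test)
}

stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Sweep the inverse regularization strength C
#'
#' Performs one stratified 80:20 train/test split (by `split_seed`), fits
#' the L1-logistic path over the C grid on the training part, and records
#' per C the number of nonzero coefficients and the test-set accuracy; a
#' 5-fold cross-validated accuracy on the training part is computed
#' alongside as a diagnostic curve.  At C values small enough to zero all
#' coefficients the model predicts one constant class, so the test
#' accuracy equals that class's fraction of the test set.
#'
#' @param m A labeled, imputed, scaled [feature_matrix].
#' @param grid Increasing C values (default the fine grid 0.01..1 step
#'   0.001).
#' @param split_seed Seed of the stratified split (and CV folds).
#' @param cv_folds Number of CV folds on the training part.
#' @param tol Solver threshold (see [fit_l1_lr()]).
#' @return An object of class `sweep_result`: list with `grid`,
#'   `nonzero_counts`, `acc_test`, `acc_cv`, `split_seed`, `test_idx`,
#'   and the training data used for refits.
#' @export
sweep_C <- function(m, grid = seq(0.01, 1, by = 0.001), split_seed = 1L,
                    cv_folds = 5L, tol = 1e-9) {
  if (!length(grid)) stop("empty C grid")
  if (is.unsorted(grid, strictly = TRUE)) stop("C grid must be strictly increasing")
  if (is.null(m$y)) stop("sweep_C() needs labels")
  y <- m$y; X <- m$X
  test_idx <- stratified_split(y, 0.2, split_seed)
  if (length(unique(y[test_idx])) < 2 || length(unique(y[-test_idx])) < 2) {
    stop("both classes must be present in both split parts")
  }
  Xtr <- X[-test_idx, , drop = FALSE]; ytr <- y[-test_idx]
  Xte <- X[test_idx, , drop = FALSE];  yte <- y[test_idx]

  path <- path_fit(Xtr, ytr, grid, tol)
  nonzero <- colSums(path$beta != 0)
  acc_test <- vapply(seq_along(grid), function(k) {
    pred <- as.integer(plogis(as.numeric(Xte %*% path$beta[, k]) + path$a0[k]) >= 0.5)
    accuracy(confusion_counts(yte, pred))
  }, 0)

  fold <- stratified_folds(ytr, cv_folds, derive_seed(split_seed, "cv"))
  acc_fold <- matrix(NA_real_, cv_folds, length(grid))
  for (f in seq_len(cv_folds)) {
    hold <- fold == f
    pf <- path_fit(Xtr[!hold, , drop = FALSE], ytr[!hold], grid, tol)
    for (k in seq_along(grid)) {
      pred <- as.integer(plogis(as.numeric(Xtr[hold, , drop = FALSE] %*%
                                             pf$beta[, k]) + pf$a0[k]) >= 0.5)
      acc_fold[f, k] <- accuracy(confusion_counts(ytr[hold], pred))
    }
  }

  structure(list(grid = grid, nonzero_counts = unname(nonzero),
                 acc_test = acc_test, acc_cv = colMeans(acc_fold),
                 split_seed = split_seed, test_idx = test_idx,
                 Xtr = Xtr, ytr = ytr, tol = tol),
            class = "sweep_result")
}

# Fit the whole lambda path in one solver call; columns follow `grid`.
path_fit <- function(X, y, grid, tol) {
  n <- nrow(X)
  lam <- 1 / (n * grid)                       # decreasing, as the solver wants
  fit <- glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                        alpha = 1, lambda = lam, standardize = FALSE,
                        thresh = tol, maxit = 5e5)
  beta <- as.matrix(fit$beta)
  beta[abs(beta) < 10 * tol] <- 0
  list(beta = beta, a0 = as.numeric(fit$a0))
}

#' @exportS3Method base::print
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", length(x$grid), " C values in [",
      min(x$grid), ", ", max(x$grid), "], test accuracy ",
      round(min(x$acc_test), 3), "..", round(max(x$acc_test), 3), "\n", sep = "")
  invisible(x)
}

#' Select C: fewest features at near-maximal accuracy
#'
#' Chooses the smallest grid C whose accuracy is within `epsilon` of the
#' maximum over the grid — the sparsest model that still attains
#' (relatively) high prediction accuracy — and refits the model at that C
#' on the training part of the split.  Selection uses the held-out test
#' accuracy by default; `select_on = "cv"` switches to the
#' cross-validation curve.
#'
#' @param s A `sweep_result` from [sweep_C()].
#' @param epsilon Accuracy slack from the grid maximum (default 0.005).
#' @param select_on `"test"` or `"cv"`.
#' @return List with `chosen_C`, `accuracy`, `model` (an `lr_model`), and
#'   `n_selected`.
#' @export
select_C <- function(s, epsilon = 0.005, select_on = c("test", "cv")) {
  select_on <- match.arg(select_on)
  acc <- if (select_on == "test") s$acc_test else s$acc_cv
  k <- which(acc >= max(acc) - epsilon)[1]
  chosen <- s$grid[k]
  model <- if (!is.null(s$Xtr)) fit_l1_lr(s$Xtr, s$ytr, chosen, tol = s$tol) else NULL
  list(chosen_C = chosen, accuracy = acc[k], model = model,
       n_selected = if (!is.null(model)) sum(model$w != 0) else s$nonzero_counts[k])
}

#' Ranked report of selected features
#'
#' Nonzero coefficients sorted by decreasing absolute value; the sign
#' marks the direction of association with the positive
#' (ribosome-associated) class.
#'
#' @param model An `lr_model`.
#' @param names Optional feature names (default the model's).
#' @return `data.frame` with `rank`, `feature`, `coef`, `sign`; empty
#'   (with a warning) for an all-zero model.
#' @export
report_features <- function(model, names = NULL) {
  w <- model$w
  if (!is.null(names)) names(w) <- names
  nz <- which(w != 0)
  if (!length(nz)) {
    warning("all coefficients are zero; empty feature report")
    return(data.frame(rank = integer(0), feature = character(0),
                      coef = numeric(0), sign = character(0)))
  }
  ord <- nz[order(-abs(w[nz]), names(w)[nz])]
  data.frame(rank = seq_along(ord), feature = names(w)[ord],
             coef = unname(w[ord]), sign = ifelse(w[ord] > 0, "+", "-"),
             stringsAsFactors = FALSE, row.names = NULL)
}
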