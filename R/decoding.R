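## Linear soft-margin SVM (dual QP via quadprog) and leave-one-run-out
## near/far decoding, trained at the highest signal level and tested at all
## levels.

#' Data-dependent SVM cost parameter
#'
#' `C = n_folds / sum_i ||x_i||^2`: the number of cross-validation folds
#' divided by the total squared norm of the training patterns. The
#' alternative reading (`divide = TRUE`) gives
#' `C = 1 / (sum ||x||^2 * n_folds)`; which one is used is recorded in
#' decoding output metadata.
#'
#' @param train_patterns Training matrix (patterns x voxels).
#' @param n_folds Number of cross-validation folds.
#' @param divide If `TRUE`, divide (rather than multiply) by `n_folds`.
#' @return Positive scalar cost.
#' @export
svm_cost <- function(train_patterns, n_folds, divide = FALSE) {
  abort_if(nrow(train_patterns) < 1, "need at least one training pattern")
  ss <- sum(train_patterns^2)
  abort_if(ss == 0, "all-zero training data: cost undefined")
  if (divide) 1 / (ss * n_folds) else n_folds / ss
}

#' Train a linear soft-margin SVM
#'
#' Solves the dual quadratic program of the L1 soft-margin SVM with a linear
#' kernel (box constraint `0 <= alpha_i <= C`, equality `sum alpha_i y_i =
#' 0`) with `quadprog::solve.QP`, ridging the Gram matrix by a tiny multiple
#' of its mean diagonal for strict positive-definiteness. Deterministic: no
#' randomized initialization.
#'
#' @param patterns Numeric matrix (patterns x voxels).
#' @param labels Vector with exactly two distinct values; the
#'   lexicographically first sorted label is the negative class.
#' @param C Positive cost parameter.
#' @return An `svm_model`: list with `weights`, `bias`, `classes` (sorted),
#'   `alpha`, `C`. Prediction score is `x . weights + bias`; positive scores
#'   predict `classes[2]`, and a score of exactly 0 resolves to the
#'   lexicographically first class `classes[1]`.
#' @export
train_linear_svm <- function(patterns, labels, C) {
  x <- as.matrix(patterns)
  classes <- sort(unique(labels))
  abort_if(length(classes) != 2,
           "training needs exactly two classes, got %d", length(classes))
  abort_if(C <= 0, "C must be positive")
  y <- ifelse(labels == classes[2], 1, -1)
  n <- nrow(x)
  K <- tcrossprod(x)
  D <- (y %o% y) * K
  ridge <- max(mean(diag(D)), 1) * 1e-10
  Dmat <- D + diag(ridge, n)
  # constraints: sum alpha*y = 0 (meq), alpha >= 0, alpha <= C
  Amat <- cbind(y, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat, rep(1, n), Amat, bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  w <- drop(crossprod(x, alpha * y))
  # bias from margin support vectors; fall back to the KKT midpoint
  tol <- C * 1e-6
  on_margin <- which(alpha > tol & alpha < C - tol)
  f <- drop(x %*% w)
  b <- if (length(on_margin) > 0) {
    mean(y[on_margin] - f[on_margin])
  } else {
    # KKT interval for b when no alpha lies strictly inside (0, C)
    lo_b <- suppressWarnings(max(c(1 - f[y == 1 & alpha <= tol],
                                   -1 - f[y == -1 & alpha >= C - tol])))
    up_b <- suppressWarnings(min(c(-1 - f[y == -1 & alpha <= tol],
                                   1 - f[y == 1 & alpha >= C - tol])))
    if (!is.finite(lo_b)) up_b else if (!is.finite(up_b)) lo_b
    else (lo_b + up_b) / 2
  }
  structure(list(weights = w, bias = b, classes = classes, alpha = alpha,
                 C = C),
            class = "svm_model")
}

#' @export
predict.svm_model <- function(object, newdata, ...) {
  score <- drop(as.matrix(newdata) %*% object$weights) + object$bias
  ifelse(score > 0, object$classes[2], object$classes[1])
}

#' Leave-one-run-out decoding of depth sign
#'
#' Each run serves once as the held-out test set. The classifier is trained
#' on near/far patterns at `train_level` (the highest signal level, where
#' training data are most reliable) from the remaining runs, then tested on
#' the held-out run at every level. The cost parameter is computed from each
#' fold's training patterns via [svm_cost] with `n_folds` equal to the run
#' count. Chance for the balanced binary problem is 0.5.
#'
#' @param ps A normalized `pattern_set`.
#' @param train_level Signal level used for training (default: maximum
#'   level present).
#' @param divide_cost Passed to [svm_cost].
#' @param shuffle_train_labels Optional function called per fold with the
#'   training label vector, returning a (possibly permuted) label vector —
#'   used by the permutation-null machinery. Default `NULL` (no shuffling).
#' @return A `decoding_result`: list with `accuracy_by_level` (named numeric),
#'   `per_fold` (fold x level matrix), `levels`, `train_level`, `n_train`,
#'   `n_test_per_level`, `cost` (per fold), `n_folds`.
#' @export
run_locv <- function(ps, train_level = NULL, divide_cost = FALSE,
                     shuffle_train_labels = NULL) {
  stopifnot(inherits(ps, "pattern_set"))
  runs <- sort(unique(ps$run_id))
  abort_if(length(runs) < 2, "leave-one-run-out needs >= 2 runs")
  levels_all <- sort(unique(ps$level))
  if (is.null(train_level)) train_level <- max(levels_all)
  for (r in runs) {
    abort_if(!any(ps$run_id == r & ps$level == train_level),
             "run %s has no patterns at the training level %s", r, train_level)
  }
  n_folds <- length(runs)
  per_fold <- matrix(NA_real_, n_folds, length(levels_all),
                     dimnames = list(paste0("run", runs), levels_all))
  costs <- numeric(n_folds)
  n_train <- NA_integer_; n_test <- NA_integer_
  for (i in seq_along(runs)) {
    held <- runs[i]
    tr_idx <- which(ps$run_id != held & ps$level == train_level)
    xtr <- ps$patterns[tr_idx, , drop = FALSE]
    ytr <- ps$sign[tr_idx]
    if (!is.null(shuffle_train_labels)) ytr <- shuffle_train_labels(ytr)
    costs[i] <- svm_cost(xtr, n_folds, divide = divide_cost)
    model <- train_linear_svm(xtr, ytr, costs[i])
    n_train <- length(tr_idx)
    for (j in seq_along(levels_all)) {
      te_idx <- which(ps$run_id == held & ps$level == levels_all[j])
      if (length(te_idx) == 0) next
      pred <- predict(model, ps$patterns[te_idx, , drop = FALSE])
      per_fold[i, j] <- mean(pred == ps$sign[te_idx])
      n_test <- length(te_idx)
    }
  }
  acc <- colMeans(per_fold, na.rm = TRUE)
  structure(list(accuracy_by_level = acc, per_fold = per_fold,
                 levels = levels_all, train_level = train_level,
                 n_train = n_train, n_test_per_level = n_test,
                 cost = costs, n_folds = n_folds,
                 cost_rule = if (divide_cost) "1/(sum_sq*n_folds)"
                             else "n_folds/sum_sq"),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding_result: %d folds, trained at level %s (n_train = %d, %d test/level)\n",
              x$n_folds, x$train_level, x$n_train, x$n_test_per_level))
  print(round(x$accuracy_by_level, 3))
  invisible(x)
}

#' Write a decoding result as TSV plus JSON metadata
#'
#' @param res A `decoding_result`.
#' @param path Output TSV path; metadata goes to `<path>.json`.
#' @export
write_decoding_result <- function(res, path) {
  df <- data.frame(level = res$levels, mean_accuracy = res$accuracy_by_level)
  df <- cbind(df, t(res$per_fold))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(train_level = res$train_level,
                            n_folds = res$n_folds, cost = res$cost,
                            cost_rule = res$cost_rule),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
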