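## Permutation null distributions for classifier accuracy, nearest-rank
## centiles, the significance criterion, and the chance band anchoring the
## fMR-metric lower asymptote.

#' Permutation null distribution of decoding accuracy
#'
#' Repeats the full leave-one-run-out procedure with the training labels
#' randomly permuted within each fold's training set (test labels intact)
#' and records the mean accuracy at the training level. Each iteration uses
#' a seed derived from `seed`, so individual iterations are reproducible.
#'
#' @param ps A normalized `pattern_set`.
#' @param train_level Training signal level (default: maximum present).
#' @param n_iter Number of permutations (999 for the standard criterion).
#' @param seed Integer seed.
#' @param shuffle_test If `TRUE`, test labels are shuffled too (sensitivity
#'   variant; default `FALSE`).
#' @return A `null_distribution`: list with `accuracies` (length `n_iter`),
#'   `n_iter`, `seed`, `train_level`.
#' @export
permutation_null <- function(ps, train_level = NULL, n_iter = 999, seed = 1L,
                             shuffle_test = FALSE) {
  abort_if(n_iter < 1, "n_iter must be >= 1")
  if (is.null(train_level)) train_level <- max(ps$level)
  acc <- vapply(seq_len(n_iter), function(it) {
    it_seed <- derive_seed(seed, it)
    fold <- 0L
    shuf <- function(y) {
      fold <<- fold + 1L
      with_seed(derive_seed(it_seed, fold), sample(y))
    }
    ps_it <- ps
    if (shuffle_test) {
      ps_it$sign <- with_seed(derive_seed(it_seed, 1000L), sample(ps$sign))
    }
    res <- run_locv(ps_it, train_level = train_level,
                    shuffle_train_labels = shuf)
    unname(res$accuracy_by_level[as.character(train_level)])
  }, numeric(1))
  structure(list(accuracies = acc, n_iter = n_iter, seed = seed,
                 train_level = train_level),
            class = "null_distribution")
}

#' Nearest-rank centile of a null distribution
#'
#' Uses the nearest-rank (ceiling) rule: the `ceiling(q/100 * n)`-th order
#' statistic of the sorted values; `q = 0` returns the minimum.
#'
#' @param nd A `null_distribution` (or numeric vector).
#' @param q Percentile in `[0, 100]`.
#' @return The centile value.
#' @export
centile <- function(nd, q) {
  vals <- if (inherits(nd, "null_distribution")) nd$accuracies else nd
  abort_if(length(vals) == 0, "empty distribution")
  abort_if(q < 0 || q > 100, "q must be in [0, 100]")
  s <- sort(vals)
  s[max(1L, ceiling(q / 100 * length(s)))]
}

#' Chance band of a null distribution
#'
#' The 32nd to 68th centile interval (approximately +/- one standard error
#' around the median for a roughly normal null), used to constrain the lower
#' asymptote of fMR-metric fits to originate within chance performance.
#'
#' @param nd A `null_distribution` (or numeric vector).
#' @return Numeric `c(low, high)`.
#' @export
chance_band <- function(nd) {
  vals <- if (inherits(nd, "null_distribution")) nd$accuracies else nd
  abort_if(length(vals) < 2, "need >= 2 values for a band")
  c(low = centile(vals, 32), high = centile(vals, 68))
}

#' Significance criterion from a permutation null
#'
#' One-tailed criterion at the `100 * (1 - alpha / n_comparisons)` nearest-
#' rank centile — with the defaults (`alpha = 0.05`, 12 regions of interest
#' Bonferroni-corrected, one-tailed) this is the upper 99.5(8)th centile;
#' `n_comparisons = 10` gives exactly the 99.5th.
#'
#' @param nd A `null_distribution`.
#' @param q Centile used as the criterion (default 99.5).
#' @return List with `criterion` (accuracy cutoff) and `q`.
#' @export
significance_criterion <- function(nd, q = 99.5) {
  list(criterion = centile(nd, q), q = q)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution: %d permutations at level %s; median = %.3f, 99.5th centile = %.3f\n",
              x$n_iter, x$train_level, stats::median(x$accuracies),
              centile(x, 99.5)))
  invisible(x)
}

#' Write a null distribution as single-column TSV plus JSON metadata
#'
#' @param nd A `null_distribution`.
#' @param path Output TSV path; metadata goes to `<path>.json`.
#' @export
write_null_distribution <- function(nd, path) {
  utils::write.table(data.frame(accuracy = nd$accuracies), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = nd$seed, n_iter = nd$n_iter,
                            train_level = nd$train_level),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
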