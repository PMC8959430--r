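#' Multi-class confusion matrix
#'
#' @param truth,predicted Vectors of true and predicted labels.
#' @param levels Class levels (default: union of both, sorted as a factor).
#' @return A `kdemg_confusion` object: integer matrix, rows = truth,
#'   columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  if (length(truth) != length(predicted) || length(truth) == 0) {
    abort("`truth` and `predicted` must be non-empty and aligned.",
          class = "kdemg_error_bad_input")
  }
  lev <- levels %||% levels(factor(c(as.character(truth),
                                     as.character(predicted))))
  m <- table(factor(as.character(truth), levels = as.character(lev)),
             factor(as.character(predicted), levels = as.character(lev)))
  structure(unclass(m), class = "kdemg_confusion",
            dimnames = list(truth = rownames(m), predicted = colnames(m)))
}

#' Per-class and aggregate classification metrics
#'
#' From a confusion matrix, derives per class `i` the counts `TP_i`, `TN_i`,
#' `FP_i`, `FN_i` and the metrics
#' precision `PR_i = TP_i / (TP_i + FP_i)`,
#' recall `RL_i = TP_i / (TP_i + FN_i)`,
#' accuracy `Acc_i = (TP_i + TN_i) / total`, and
#' F-score `F_i = 2 PR_i RL_i / (PR_i + RL_i)`; plus the aggregates: macro-F
#' (mean of `F_i`; `NaN` when any class has `TP_i = 0`, i.e. the F-score is
#' undefined and deliberately not zero-substituted), micro precision/recall
#' (pooled counts), micro-F, and overall accuracy. In single-label
#' multi-class scoring the micro-F, micro precision, micro recall and overall
#' accuracy coincide.
#'
#' @param cm A `kdemg_confusion` matrix.
#' @return A `kdemg_metrics` object; see [tidy.kdemg_metrics()] and
#'   [glance.kdemg_metrics()].
#' @export
metrics_report <- function(cm) {
  if (!inherits(cm, "kdemg_confusion") || sum(cm) == 0) {
    abort("Need a non-empty confusion matrix.",
          class = "kdemg_error_bad_input")
  }
  total <- sum(cm)
  tp <- unname(diag(cm))
  fp <- unname(colSums(cm)) - tp
  fn <- unname(rowSums(cm)) - tp
  tn <- total - tp - fp - fn
  pr <- tp / (tp + fp)
  rl <- tp / (tp + fn)
  f1 <- 2 * pr * rl / (pr + rl)
  per_class <- tibble(
    class = rownames(cm), tp = as.integer(tp), tn = as.integer(tn),
    fp = as.integer(fp), fn = as.integer(fn),
    precision = pr, recall = rl,
    accuracy = (tp + tn) / total, f1 = f1
  )
  micro_pr <- sum(tp) / sum(tp + fp)
  micro_rl <- sum(tp) / sum(tp + fn)
  # harmonic mean, with the 0/0 continuity convention so that
  # micro-F == pooled precision == pooled recall == accuracy always holds
  micro_f <- if (micro_pr + micro_rl > 0) {
    2 * micro_pr * micro_rl / (micro_pr + micro_rl)
  } else 0
  structure(
    list(per_class = per_class,
         macro_f = mean(f1),           # NaN propagates by design
         micro_f = micro_f,
         micro_precision = micro_pr, micro_recall = micro_rl,
         accuracy = sum(tp) / total,
         confusion = cm),
    class = "kdemg_metrics"
  )
}

#' @export
print.kdemg_metrics <- function(x, ...) {
  cat(sprintf("<kdemg_metrics> %d classes, accuracy %.4f, macro-F %s\n",
              nrow(x$per_class), x$accuracy,
              ifelse(is.nan(x$macro_f), "NaN", sprintf("%.4f", x$macro_f))))
  invisible(x)
}

#' Per-class metric rows
#' @param x A `kdemg_metrics` object.
#' @param ... Unused.
#' @export
tidy.kdemg_metrics <- function(x, ...) x$per_class

#' One-row aggregate metric summary
#' @param x A `kdemg_metrics` object.
#' @param ... Unused.
#' @export
glance.kdemg_metrics <- function(x, ...) {
  tibble(accuracy = x$accuracy, macro_f = x$macro_f, micro_f = x$micro_f,
         micro_precision = x$micro_precision, micro_recall = x$micro_recall)
}

#' Repeated hold-out split scheme over six repetitions
#'
#' The three fixed train/test partitions used to validate against six
#' movement repetitions: each split trains on four repetitions and tests on
#' two, and each repetition is tested exactly once across the three splits.
#'
#' @param n_repetitions Must be 6.
#' @return A tibble with columns `split`, `test` (list of repetition ids),
#'   `train` (list).
#' @examples
#' make_repeated_holdout()
#' @export
make_repeated_holdout <- function(n_repetitions = 6L) {
  if (n_repetitions != 6L) {
    abort("The repeated hold-out scheme is defined for exactly 6 repetitions.",
          class = "kdemg_error_scheme")
  }
  tibble(
    split = 1:3,
    test = list(c(1L, 4L), c(2L, 5L), c(3L, 6L)),
    train = list(c(2L, 3L, 5L, 6L), c(1L, 3L, 4L, 6L), c(1L, 2L, 4L, 5L))
  )
}

#' Seeded stratified k-fold assignment
#'
#' @param labels Class label per row.
#' @param k Number of folds (default 4).
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per row; folds are
#'   near-equal within each class (sizes differ by at most 1).
#' @export
make_kfold <- function(labels, k = 4L, seed = 1L) {
  if (any(table(labels) < k)) {
    abort("Every class needs at least k rows for stratified k-fold.",
          class = "kdemg_error_stratification")
  }
  stratified_folds(factor(labels), k, seed)
}

#' Fleiss' kappa with a large-sample confidence interval
#'
#' Chance-corrected agreement among a fixed number of raters assigning items
#' to categories. The input is an items-by-categories count matrix (each row
#' sums to the number of raters). Returns the kappa, its large-sample
#' standard error under the null of chance agreement, and a 95% CI.
#'
#' @param ratings Matrix, rows = items, columns = categories, entries =
#'   number of raters choosing that category.
#' @return List with `kappa`, `se`, `ci95` (length-2 vector), `n_items`,
#'   `n_raters`.
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  n_raters <- unique(rowSums(ratings))
  if (length(n_raters) != 1L || n_raters < 2 || ncol(ratings) < 2) {
    abort("Need >= 2 raters (constant per item) and >= 2 categories.",
          class = "kdemg_error_bad_input")
  }
  N <- nrow(ratings)
  n <- n_raters
  pj <- colSums(ratings) / (N * n)
  if (sum(pj > 0) < 2) {
    abort("All ratings in a single category: kappa undefined.",
          class = "kdemg_error_degenerate")
  }
  Pi <- (rowSums(ratings^2) - n) / (n * (n - 1))
  Pbar <- mean(Pi)
  Pe <- sum(pj^2)
  kappa <- (Pbar - Pe) / (1 - Pe)
  # Fleiss (1971) large-sample SE under chance agreement
  se <- sqrt(2 / (N * n * (n - 1))) *
    sqrt(Pe - (2 * n - 3) * Pe^2 + 2 * (n - 2) * sum(pj^3)) / (1 - Pe)
  list(kappa = kappa, se = se,
       ci95 = kappa + c(-1, 1) * stats::qnorm(0.975) * se,
       n_items = N, n_raters = n)
}

#' McNemar's test on paired classifier correctness
#'
#' Compares two classifiers on the same scored rows via their discordant
#' pairs. With fewer than 25 discordant pairs the exact binomial two-sided
#' test is used; otherwise the chi-square approximation with continuity
#' correction. With no discordant pairs, `p = 1` by convention.
#'
#' @param correct_a,correct_b Logical vectors: whether each classifier got
#'   each row right.
#' @return List with `statistic` (chi-square, `NA` for the exact branch),
#'   `p_value`, `n_discordant`, `method`.
#' @export
mcnemar_test <- function(correct_a, correct_b) {
  if (length(correct_a) != length(correct_b) || length(correct_a) == 0) {
    abort("Vectors must be non-empty and aligned.",
          class = "kdemg_error_bad_input")
  }
  b <- sum(correct_a & !correct_b)   # a right, b wrong
  c_ <- sum(!correct_a & correct_b)  # b right, a wrong
  nd <- b + c_
  if (nd == 0) {
    return(list(statistic = 0, p_value = 1, n_discordant = 0L,
                method = "exact"))
  }
  if (nd < 25) {
    p <- min(1, 2 * pbinom(min(b, c_), nd, 0.5))
    list(statistic = NA_real_, p_value = p, n_discordant = nd,
         method = "exact")
  } else {
    stat <- (abs(b - c_) - 1)^2 / nd
    list(statistic = stat, p_value = stats::pchisq(stat, df = 1,
                                                   lower.tail = FALSE),
         n_discordant = nd, method = "chi-square")
  }
}
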