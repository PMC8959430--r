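feature_columns <- function(table) {
  setdiff(names(table), c("subject", "label", "repetition", "window_id"))
}

as_xy <- function(table, features = NULL) {
  feats <- features %||% feature_columns(table)
  list(x = as.matrix(table[feats]),
       y = factor(table$label),
       features = feats)
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

#' Train the LDA, RBF-SVM, and MLP base learners
#'
#' Fits the three base classifiers used for ensemble fusion:
#'
#' * **LDA** -- linear discriminant analysis;
#' * **SVM** -- RBF kernel with probability outputs; the soft-margin cost and
#'   kernel width are chosen by a seeded stratified 3-fold grid search over
#'   `C` in \{0.1, 1, 10, 100\} and `gamma` in \{0.01, 0.1, 1, 10\};
#' * **MLP** -- single hidden layer of 15 units with softmax outputs,
#'   seeded.
#'
#' @param train Feature tibble with a `label` column.
#' @param features Feature columns to use (default: all).
#' @param seed Integer seed controlling the SVM grid search, SVM probability
#'   calibration, and MLP initialization.
#' @param svm_grid Named list with `cost` and `gamma` candidate vectors.
#' @param mlp_size Hidden-layer width (default 15).
#' @param mlp_maxit MLP training iterations.
#' @return A `kdemg_learners` object (list of fitted learners with class
#'   levels and the feature list).
#' @export
train_base_learners <- function(train, features = NULL, seed = 1L,
                                svm_grid = list(cost = c(0.1, 1, 10, 100),
                                                gamma = c(0.01, 0.1, 1, 10)),
                                mlp_size = 15L, mlp_maxit = 300L) {
  xy <- as_xy(train, features)
  if (nlevels(xy$y) < 2) {
    abort("Need at least two classes.", class = "kdemg_error_bad_input")
  }
  if (any(table(xy$y) < 2)) {
    abort("Every class needs at least two training rows.",
          class = "kdemg_error_stratification")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))

  lda_fit <- MASS::lda(xy$x, grouping = xy$y)

  set.seed(seed)
  best <- tune_svm_grid(xy$x, xy$y, svm_grid, seed = seed)
  set.seed(seed)
  svm_fit <- e1071::svm(xy$x, xy$y, kernel = "radial", cost = best$cost,
                        gamma = best$gamma, probability = TRUE)

  set.seed(seed)
  mlp_fit <- nnet::nnet(xy$x, nnet::class.ind(xy$y), size = mlp_size,
                        softmax = TRUE, maxit = mlp_maxit, decay = 1e-4,
                        trace = FALSE, MaxNWts = 100000L)

  structure(
    list(
      lda = list(type = "lda", model = lda_fit),
      svm = list(type = "svm", model = svm_fit, cost = best$cost,
                 gamma = best$gamma),
      mlp = list(type = "mlp", model = mlp_fit, size = mlp_size),
      levels = levels(xy$y), features = xy$features, seed = seed
    ),
    class = "kdemg_learners"
  )
}

# Stratified 3-fold grid search maximizing held-out accuracy; falls back to
# training accuracy when a class is too small to stratify into 3 folds.
tune_svm_grid <- function(x, y, grid, seed) {
  folds <- if (min(table(y)) >= 3) {
    stratified_folds(y, 3L, seed)
  } else NULL
  combos <- expand.grid(cost = grid$cost, gamma = grid$gamma)
  acc <- vapply(seq_len(nrow(combos)), function(i) {
    co <- combos$cost[i]; ga <- combos$gamma[i]
    if (is.null(folds)) {
      set.seed(seed)
      fit <- e1071::svm(x, y, kernel = "radial", cost = co, gamma = ga)
      mean(predict(fit, x) == y)
    } else {
      mean(vapply(seq_len(3L), function(f) {
        tr <- folds != f
        set.seed(seed)
        fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                          cost = co, gamma = ga)
        mean(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
      }, numeric(1)))
    }
  }, numeric(1))
  best <- which.max(acc)  # first max: deterministic preference for low cost
  list(cost = combos$cost[best], gamma = combos$gamma[best],
       accuracy = acc[best])
}

# Stratified fold assignment that also balances overall fold sizes: each
# class's remainder rows go to the currently least-filled folds.
stratified_folds <- function(y, k, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(length(y))
  fold_sizes <- integer(k)
  for (cl in levels(factor(y))) {
    idx <- which(y == cl)
    base <- length(idx) %/% k
    rem <- length(idx) %% k
    counts <- rep(base, k)
    if (rem > 0) {
      extra <- order(fold_sizes)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
    fold[idx] <- sample(rep(seq_len(k), counts))
    fold_sizes <- fold_sizes + counts
  }
  fold
}

#' Predict with the fitted base learners
#'
#' @param learners A `kdemg_learners` object.
#' @param newdata Feature tibble.
#' @return List of per-learner outputs, each a list with `labels` (character)
#'   and `posteriors` (row-stochastic matrix, columns in `learners$levels`
#'   order).
#' @export
predict_base_learners <- function(learners, newdata) {
  x <- as.matrix(newdata[learners$features])
  lev <- learners$levels
  out <- list()

  p <- predict(learners$lda$model, x)
  out$lda <- list(labels = as.character(p$class),
                  posteriors = align_cols(p$posterior, lev))

  pr <- predict(learners$svm$model, x, probability = TRUE)
  post <- attr(pr, "probabilities")
  out$svm <- list(labels = as.character(pr),
                  posteriors = align_cols(post, lev))

  post <- predict(learners$mlp$model, x)
  colnames(post) <- colnames(learners$mlp$model$fitted.values)
  post <- align_cols(post, lev)
  out$mlp <- list(labels = lev[max.col(post, ties.method = "first")],
                  posteriors = post)
  out
}

align_cols <- function(m, lev) {
  m <- m[, lev, drop = FALSE]
  m / rowSums(m)
}

#' Fit a Behavioral Knowledge Space fusion table
#'
#' Indexes every training row by the tuple of base-learner decisions and
#' stores, per tuple, the counts of the true classes observed with it. At
#' prediction time the majority true class of the row's tuple is returned.
#'
#' @param outputs List of base-learner outputs
#'   (from [predict_base_learners()] on the training rows).
#' @param truth True labels aligned with the outputs.
#' @return A `kdemg_bks` object: list with `cells` (named list of class-count
#'   vectors), `levels`.
#' @export
bks_fit <- function(outputs, truth) {
  n <- length(truth)
  if (n == 0) abort("Empty training set.", class = "kdemg_error_bad_input")
  labels <- do.call(cbind, lapply(outputs, `[[`, "labels"))
  if (nrow(labels) != n) {
    abort("Outputs not aligned with truth.", class = "kdemg_error_bad_input")
  }
  keys <- apply(labels, 1L, paste, collapse = "|")
  lev <- levels(factor(truth))  # numeric labels sort numerically
  cells <- lapply(split(as.character(truth), keys), function(tr) {
    table(factor(tr, levels = lev))
  })
  structure(list(cells = cells, levels = lev), class = "kdemg_bks")
}

#' Predict by Behavioral Knowledge Space lookup
#'
#' Looks up each row's decision tuple; the cell's majority true class is
#' returned. Tuples never seen in training, and cells whose majority is tied,
#' fall back to the class with the highest mean posterior across learners.
#'
#' @param outputs List of base-learner outputs on the rows to score.
#' @param table A `kdemg_bks` object.
#' @return Character vector of fused labels.
#' @export
bks_predict <- function(outputs, table) {
  labels <- do.call(cbind, lapply(outputs, `[[`, "labels"))
  keys <- apply(labels, 1L, paste, collapse = "|")
  mean_post <- Reduce(`+`, lapply(outputs, `[[`, "posteriors")) /
    length(outputs)
  vapply(seq_along(keys), function(i) {
    cell <- table$cells[[keys[i]]]
    if (!is.null(cell)) {
      mx <- max(cell)
      winners <- names(cell)[cell == mx]
      if (length(winners) == 1L) return(winners)
    }
    colnames(mean_post)[which.max(mean_post[i, ])]
  }, character(1))
}

#' Gradient-boosted trees for simultaneous-movement classification
#'
#' Multiclass gradient-boosted decision trees with the configuration used
#' for two-movement (simultaneous) classification: 600 trees, maximum depth
#' 18, learning rate 0.1. Deterministic given the seed (single thread).
#'
#' @param train Feature tibble with a `label` column.
#' @param features Feature columns (default all).
#' @param n_estimators,max_depth,learning_rate Boosting hyperparameters.
#' @param seed Integer seed.
#' @param nthread Threads for xgboost (default 1 for determinism).
#' @return A `kdemg_boost` object: list with `model`, `levels`, `features`,
#'   `params`.
#' @export
train_boosted_trees <- function(train, features = NULL, n_estimators = 600L,
                                max_depth = 18L, learning_rate = 0.1,
                                seed = 1L, nthread = 1L) {
  xy <- as_xy(train, features)
  if (nlevels(xy$y) < 2) {
    abort("Need at least two classes.", class = "kdemg_error_bad_input")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(xy$x, label = as.integer(xy$y) - 1L)
  params <- list(objective = "multi:softprob",
                 num_class = nlevels(xy$y),
                 max_depth = max_depth, eta = learning_rate,
                 nthread = nthread, tree_method = "hist",
                 seed = seed)
  model <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = n_estimators, verbose = 0)
  structure(
    list(model = model, levels = levels(xy$y), features = xy$features,
         params = list(n_estimators = n_estimators, max_depth = max_depth,
                       learning_rate = learning_rate, seed = seed)),
    class = "kdemg_boost"
  )
}

#' @export
predict.kdemg_boost <- function(object, newdata, ...) {
  x <- as.matrix(newdata[object$features])
  post <- predict(object$model, xgboost::xgb.DMatrix(x))
  if (is.null(dim(post))) {
    post <- matrix(post, ncol = length(object$levels), byrow = TRUE)
  }
  colnames(post) <- object$levels
  list(labels = object$levels[max.col(post, ties.method = "first")],
       posteriors = post)
}

#' @export
print.kdemg_learners <- function(x, ...) {
  cat(sprintf(
    "<kdemg_learners> LDA + SVM(RBF, C=%g, gamma=%g) + MLP(%d hidden), %d classes\n",
    x$svm$cost, x$svm$gamma, x$mlp$size, length(x$levels)))
  invisible(x)
}

#' @export
print.kdemg_boost <- function(x, ...) {
  cat(sprintf("<kdemg_boost> %d trees, depth %d, eta %g, %d classes\n",
              x$params$n_estimators, x$params$max_depth,
              x$params$learning_rate, length(x$levels)))
  invisible(x)
}
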