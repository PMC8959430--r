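# Filter, standardize with per-subject pooled statistics (so relative
# movement amplitudes survive), optionally keep the contraction's middle
# third.
preprocess_records <- function(records, low_hz, high_hz, order,
                               take_middle_third = TRUE) {
  records <- purrr::map(records, bandpass_filter, low_hz = low_hz,
                        high_hz = high_hz, order = order)
  records <- standardize_dataset(records)
  if (take_middle_third) records <- purrr::map(records, middle_third)
  records
}

split_table <- function(table, test_reps) {
  list(train = dplyr::filter(table, !(.data$repetition %in% test_reps)),
       test = dplyr::filter(table, .data$repetition %in% test_reps))
}

#' Sequential (single-movement) classification experiment
#'
#' Full offline pipeline on conventional-control data: band-pass filter and
#' standardize each record, keep the middle third of the contraction, cut it
#' into sliding windows, compute the per-channel KDE features (TMD, ED,
#' TMAVDD), select features by CFS with best-first search on each training
#' split, train the LDA/SVM/MLP base learners, fuse them with a Behavioral
#' Knowledge Space table, and score the three repeated hold-out splits.
#'
#' @param records List of [emg_record()]s with 6 repetitions per movement;
#'   if `NULL`, a synthetic dataset is generated from `synth` with seeds
#'   derived from `seed`.
#' @param synth A [synthetic_config()] used when `records` is `NULL`.
#' @param seed Integer seed controlling synthesis and all stochastic
#'   training components.
#' @param window A [window_spec()] applied within the middle third.
#' @param trim,apen,n_grid Feature-extraction settings, see
#'   [extract_feature_table()].
#' @param bandpass,filter_order Preprocessing filter settings.
#' @param measure CFS correlation measure.
#' @return A `kdemg_sequential` object: `split_metrics` (tibble with one row
#'   per split: ensemble and single-learner accuracies, macro/micro F),
#'   `mean_accuracy`, `ensemble_accuracy`, `best_single_accuracy`,
#'   `selection` (per-split `kdemg_selection`s), `misclassification`
#'   (movement x split counts of test repetitions with any windowing error),
#'   `reports` (per-split `kdemg_metrics`), `seed`.
#' @export
run_sequential_experiment <- function(records = NULL,
                                      synth = synthetic_config(),
                                      seed = 42L,
                                      window = window_spec(400, 300),
                                      trim = trim_spec(),
                                      apen = apen_params(),
                                      n_grid = 512L,
                                      bandpass = c(20, 500),
                                      filter_order = 4L,
                                      measure = "symmetric_uncertainty") {
  if (is.null(records)) {
    synth$profile_seed <- as.integer(seed)
    synth$noise_seed <- as.integer(seed) + 1L
    records <- generate_dataset(synth)
  }
  records <- preprocess_records(records, bandpass[1], bandpass[2],
                                filter_order, take_middle_third = TRUE)
  table <- extract_feature_table(records, "kde", window, trim, apen, n_grid)

  scheme <- make_repeated_holdout()
  selections <- list()
  reports <- list()
  rows <- list()
  miscls <- list()
  for (i in seq_len(nrow(scheme))) {
    parts <- split_table(table, scheme$test[[i]])
    corr <- compute_correlations(parts$train, measure)
    sel <- best_first_search(corr)
    selections[[i]] <- sel

    learners <- train_base_learners(parts$train, features = sel$selected,
                                    seed = seed + i)
    tr_out <- predict_base_learners(learners, parts$train)
    te_out <- predict_base_learners(learners, parts$test)
    bks <- bks_fit(tr_out, parts$train$label)
    fused <- bks_predict(te_out, bks)

    truth <- as.character(parts$test$label)
    single_acc <- vapply(te_out, function(o) mean(o$labels == truth),
                         numeric(1))
    cm <- confusion_matrix(truth, fused, levels = learners$levels)
    rep_i <- metrics_report(cm)
    reports[[i]] <- rep_i
    rows[[i]] <- tibble(
      split = i, n_train = nrow(parts$train), n_test = nrow(parts$test),
      n_selected = length(sel$selected),
      accuracy_lda = single_acc[["lda"]], accuracy_svm = single_acc[["svm"]],
      accuracy_mlp = single_acc[["mlp"]],
      accuracy_ensemble = rep_i$accuracy,
      macro_f = rep_i$macro_f, micro_f = rep_i$micro_f
    )
    miscls[[i]] <- misclassified_by_movement(parts$test, fused, split = i)
  }
  split_metrics <- dplyr::bind_rows(rows)
  structure(
    list(split_metrics = split_metrics,
         mean_accuracy = mean(split_metrics$accuracy_ensemble),
         ensemble_accuracy = mean(split_metrics$accuracy_ensemble),
         best_single_accuracy = max(colMeans(
           split_metrics[c("accuracy_lda", "accuracy_svm", "accuracy_mlp")])),
         selection = selections,
         misclassification = dplyr::bind_rows(miscls),
         reports = reports, seed = seed),
    class = "kdemg_sequential"
  )
}

# A movement counts as misclassified in a (split, repetition) if any of its
# windows is wrongly labeled in either direction (missed: FN; stolen: FP).
misclassified_by_movement <- function(test_table, fused, split) {
  df <- tibble(label = as.character(test_table$label),
               repetition = test_table$repetition,
               predicted = as.character(fused))
  movements <- sort(unique(df$label))
  out <- purrr::map(movements, function(m) {
    reps <- sort(unique(df$repetition))
    bad <- vapply(reps, function(r) {
      d <- df[df$repetition == r, ]
      any(d$label == m & d$predicted != m) ||
        any(d$label != m & d$predicted == m)
    }, logical(1))
    tibble(split = split, movement = m, misclassified = sum(bad))
  })
  dplyr::bind_rows(out)
}

#' @export
print.kdemg_sequential <- function(x, ...) {
  cat(sprintf(
    "<kdemg_sequential> mean ensemble accuracy %.4f over %d splits (best single %.4f)\n",
    x$mean_accuracy, nrow(x$split_metrics), x$best_single_accuracy))
  print(x$split_metrics)
  invisible(x)
}

#' Online epoch-width simulation
#'
#' Emulates the online use case: the middle third of each contraction is cut
#' into non-overlapping epochs of each candidate width, only the per-channel
#' trimmed mean of density (TMD) is extracted (the cheapest of the density
#' features), and an LDA classifier is trained and scored per repeated
#' hold-out split. Mean per-epoch processing times (feature extraction plus
#' classification) are measured and reported, never asserted -- they are
#' hardware-dependent.
#'
#' @param records,synth,seed,trim,n_grid,bandpass,filter_order As in
#'   [run_sequential_experiment()].
#' @param epoch_widths_ms Epoch widths to evaluate, in milliseconds.
#' @return A `kdemg_online` object with tibble `results`: one row per epoch
#'   width (`width_ms`, `accuracy` averaged over splits, `n_epochs`,
#'   `ms_per_epoch`).
#' @export
run_online_simulation <- function(records = NULL,
                                  synth = synthetic_config(),
                                  seed = 42L,
                                  epoch_widths_ms = c(300, 200, 100, 50),
                                  trim = trim_spec(),
                                  n_grid = 512L,
                                  bandpass = c(20, 500),
                                  filter_order = 4L) {
  if (is.null(records)) {
    synth$profile_seed <- as.integer(seed)
    synth$noise_seed <- as.integer(seed) + 1L
    records <- generate_dataset(synth)
  }
  records <- preprocess_records(records, bandpass[1], bandpass[2],
                                filter_order, take_middle_third = TRUE)
  min_len <- min(vapply(records, n_samples, integer(1)))
  fs <- records[[1]]$fs
  scheme <- make_repeated_holdout()
  rows <- purrr::map(epoch_widths_ms, function(w) {
    if (round(w / 1000 * fs) > min_len) {
      warn(sprintf("Epoch width %g ms exceeds the analyzed segment; skipped.", w),
           class = "kdemg_warning_epoch_skipped")
      return(NULL)
    }
    t0 <- proc.time()[["elapsed"]]
    table <- extract_feature_table(records, "tmd",
                                   window_spec(w, w), trim = trim,
                                   n_grid = n_grid)
    feat_time <- proc.time()[["elapsed"]] - t0
    accs <- vapply(seq_len(nrow(scheme)), function(i) {
      parts <- split_table(table, scheme$test[[i]])
      xy <- as_xy(parts$train)
      fit <- MASS::lda(xy$x, grouping = xy$y)
      pred <- predict(fit, as.matrix(parts$test[xy$features]))$class
      mean(as.character(pred) == as.character(parts$test$label))
    }, numeric(1))
    tibble(width_ms = w, accuracy = mean(accs), n_epochs = nrow(table),
           ms_per_epoch = 1000 * feat_time / nrow(table))
  })
  structure(list(results = dplyr::bind_rows(rows), seed = seed),
            class = "kdemg_online")
}

#' @export
print.kdemg_online <- function(x, ...) {
  cat("<kdemg_online> TMD + LDA accuracy by epoch width\n")
  print(x$results)
  invisible(x)
}

#' Simultaneous (two-movement) classification experiment
#'
#' Nine-class pipeline for concurrent movements: band-pass filter (5--500 Hz,
#' order 8 by default) and standardize, cut contractions into 160 ms windows
#' every 40 ms, extract the KDE features, and score gradient-boosted trees
#' (600 trees, depth 18, learning rate 0.1) against LDA with stratified
#' fourfold cross-validation on the same folds, including a McNemar
#' comparison of the two classifiers.
#'
#' @param records List of [emg_record()]s (9 classes); if `NULL`, generated
#'   by [generate_simultaneous_dataset()] with seeds derived from `seed`.
#' @param synth Base [synthetic_config()] for the simultaneous protocol.
#' @param seed Integer seed.
#' @param window A [window_spec()]; default 160 ms width, 40 ms step.
#' @param trim,apen,n_grid Feature-extraction settings.
#' @param bandpass,filter_order Preprocessing filter settings.
#' @param k Cross-validation folds (default 4).
#' @param boost_args Named list overriding [train_boosted_trees()] defaults.
#' @return A `kdemg_simultaneous` object: `fold_metrics` tibble (per fold:
#'   boosted and LDA accuracy), `boost_accuracy`, `lda_accuracy`, pooled
#'   `boost_report` and `lda_report` (`kdemg_metrics` over all folds),
#'   `mcnemar` (boosted vs LDA), `seed`.
#' @export
run_simultaneous_experiment <- function(records = NULL,
                                        synth = NULL,
                                        seed = 42L,
                                        window = window_spec(160, 40),
                                        trim = trim_spec(),
                                        apen = apen_params(),
                                        n_grid = 512L,
                                        bandpass = c(5, 500),
                                        filter_order = 8L,
                                        k = 4L,
                                        boost_args = list()) {
  if (is.null(records)) {
    synth <- synth %||% synthetic_config(n_classes = 4L, n_channels = 8L,
                                         n_repetitions = 4L, fs = 1200,
                                         contraction_s = 3, rest_s = 3,
                                         band = c(20, 450))
    synth$profile_seed <- as.integer(seed)
    synth$noise_seed <- as.integer(seed) + 1L
    records <- generate_simultaneous_dataset(synth)
  }
  records <- preprocess_records(records, bandpass[1], bandpass[2],
                                filter_order, take_middle_third = FALSE)
  table <- extract_feature_table(records, "kde", window, trim, apen, n_grid)
  folds <- make_kfold(table$label, k = k, seed = seed)
  lev <- levels(factor(table$label))

  truth_all <- character(0)
  boost_all <- character(0)
  lda_all <- character(0)
  rows <- list()
  for (f in seq_len(k)) {
    train <- table[folds != f, , drop = FALSE]
    test <- table[folds == f, , drop = FALSE]
    truth <- as.character(test$label)

    boost <- do.call(train_boosted_trees,
                     c(list(train = train, seed = seed + f), boost_args))
    bp <- predict(boost, test)$labels

    xy <- as_xy(train)
    lda_fit <- MASS::lda(xy$x, grouping = xy$y)
    lp <- as.character(predict(lda_fit, as.matrix(test[xy$features]))$class)

    rows[[f]] <- tibble(fold = f, n_test = nrow(test),
                        accuracy_boost = mean(bp == truth),
                        accuracy_lda = mean(lp == truth))
    truth_all <- c(truth_all, truth)
    boost_all <- c(boost_all, bp)
    lda_all <- c(lda_all, lp)
  }
  fold_metrics <- dplyr::bind_rows(rows)
  boost_report <- metrics_report(confusion_matrix(truth_all, boost_all, lev))
  lda_report <- metrics_report(confusion_matrix(truth_all, lda_all, lev))
  structure(
    list(fold_metrics = fold_metrics,
         boost_accuracy = boost_report$accuracy,
         lda_accuracy = lda_report$accuracy,
         boost_report = boost_report, lda_report = lda_report,
         mcnemar = mcnemar_test(boost_all == truth_all,
                                lda_all == truth_all),
         seed = seed),
    class = "kdemg_simultaneous"
  )
}

#' @export
print.kdemg_simultaneous <- function(x, ...) {
  cat(sprintf(
    "<kdemg_simultaneous> boosted trees %.4f vs LDA %.4f (McNemar p = %.3g)\n",
    x$boost_accuracy, x$lda_accuracy, x$mcnemar$p_value))
  print(x$fold_metrics)
  invisible(x)
}
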