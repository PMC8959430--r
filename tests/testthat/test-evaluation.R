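test_that("metrics match hand arithmetic", {
  cm <- confusion_matrix(rep(1:2, each = 5), rep(1:2, each = 5))
  rep_ <- metrics_report(cm)
  expect_true(all(rep_$per_class$precision == 1))
  expect_true(all(rep_$per_class$recall == 1))
  expect_true(all(rep_$per_class$f1 == 1))
  expect_equal(rep_$accuracy, 1)

  # counts [[8,2],[3,7]]: PR1 = 8/11, RL1 = 0.8, F1 = 0.7619, acc = 0.75
  cm2 <- structure(matrix(c(8, 3, 2, 7), 2, 2), class = "kdemg_confusion",
                   dimnames = list(truth = c("1", "2"),
                                   predicted = c("1", "2")))
  r2 <- metrics_report(cm2)
  expect_equal(r2$per_class$precision[1], 8 / 11, tolerance = 1e-12)
  expect_equal(r2$per_class$recall[1], 0.8)
  expect_equal(r2$per_class$f1[1], 2 * (8 / 11) * 0.8 / (8 / 11 + 0.8),
               tolerance = 1e-12)
  expect_equal(r2$accuracy, 0.75)
})

test_that("micro-F equals pooled precision, recall and overall accuracy", {
  for (seed in 1:100) {
    cm <- random_cm(sample(2:8, 1), seed)
    if (sum(cm) == 0) next
    r <- metrics_report(cm)
    expect_equal(r$micro_f, r$accuracy, tolerance = 1e-12)
    expect_equal(r$micro_precision, r$accuracy, tolerance = 1e-12)
    expect_equal(r$micro_recall, r$accuracy, tolerance = 1e-12)
    # count identities
    expect_equal(sum(r$per_class$tp), sum(diag(cm)))
    expect_equal(sum(r$per_class$tp + r$per_class$fp), sum(cm))
    expect_equal(sum(r$per_class$tp + r$per_class$fn), sum(cm))
  }
})

test_that("macro-F is NaN when a class has no true positives", {
  cm <- confusion_matrix(c(1, 1, 2, 2), c(1, 1, 1, 1))
  r <- metrics_report(cm)
  expect_true(is.nan(r$per_class$f1[2]))
  expect_true(is.nan(r$macro_f))
  expect_false(is.nan(r$micro_f))

  full <- confusion_matrix(c(1, 1, 2, 2), c(1, 1, 1, 2))
  expect_false(is.nan(metrics_report(full)$macro_f))
})

test_that("the repeated hold-out scheme matches the printed splits", {
  scheme <- make_repeated_holdout()
  expect_equal(scheme$test[[1]], c(1L, 4L))
  expect_equal(scheme$test[[2]], c(2L, 5L))
  expect_equal(scheme$test[[3]], c(3L, 6L))
  expect_equal(scheme$train[[1]], c(2L, 3L, 5L, 6L))
  expect_equal(scheme$train[[2]], c(1L, 3L, 4L, 6L))
  expect_equal(scheme$train[[3]], c(1L, 2L, 4L, 5L))
  # each repetition tested exactly once; train/test disjoint
  expect_setequal(unlist(scheme$test), 1:6)
  for (i in 1:3) {
    expect_length(intersect(scheme$test[[i]], scheme$train[[i]]), 0)
  }
  expect_error(make_repeated_holdout(5), class = "kdemg_error_scheme")
})

test_that("stratified k-fold is balanced, exhaustive and seeded", {
  labels <- rep(1:4, each = 10)
  folds <- make_kfold(labels, k = 4, seed = 7)
  expect_equal(unname(table(folds)), rep(10L, 4), ignore_attr = TRUE)
  for (cl in 1:4) {
    sizes <- table(factor(folds[labels == cl], levels = 1:4))
    expect_lte(max(sizes) - min(sizes), 1)  # near-equal within class
  }
  expect_identical(folds, make_kfold(labels, k = 4, seed = 7))
  expect_false(identical(folds, make_kfold(labels, k = 4, seed = 8)))
  expect_error(make_kfold(rep(1:2, c(3, 20)), k = 4),
               class = "kdemg_error_stratification")
})

test_that("Fleiss kappa matches its definition and behaves at the extremes", {
  # perfect agreement: every item has all raters in one category
  perfect <- matrix(0, 20, 3)
  perfect[cbind(1:20, sample(1:3, 20, replace = TRUE))] <- 4
  expect_equal(fleiss_kappa(perfect)$kappa, 1)

  set.seed(70)
  n <- 10000
  a <- sample(1:4, n, replace = TRUE)
  b <- sample(1:4, n, replace = TRUE)
  ratings <- matrix(0, n, 4)
  for (i in 1:n) {
    ratings[i, a[i]] <- ratings[i, a[i]] + 1
    ratings[i, b[i]] <- ratings[i, b[i]] + 1
  }
  k <- fleiss_kappa(ratings)
  expect_lt(abs(k$kappa), 0.03)
  expect_equal(k$kappa, fleiss_oracle(ratings), tolerance = 1e-10)
  expect_lt(k$ci95[1], k$kappa)
  expect_gt(k$ci95[2], k$kappa)

  degenerate <- matrix(c(2, 0), 10, 2, byrow = TRUE)
  expect_error(fleiss_kappa(degenerate), class = "kdemg_error_degenerate")
})

test_that("McNemar test handles exact, asymptotic and degenerate branches", {
  # symmetric discordance: p = 1
  a <- c(rep(TRUE, 5), rep(FALSE, 5))
  b <- c(rep(FALSE, 5), rep(TRUE, 5))
  expect_equal(mcnemar_test(a, b)$p_value, 1)

  # 10 vs 0 discordant: exact p = 2 * 0.5^10
  a <- rep(TRUE, 10); b <- rep(FALSE, 10)
  res <- mcnemar_test(a, b)
  expect_equal(res$p_value, 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(res$method, "exact")

  # swap invariance
  set.seed(71)
  a <- runif(200) > 0.3; b <- runif(200) > 0.4
  expect_equal(mcnemar_test(a, b)$p_value, mcnemar_test(b, a)$p_value)

  # no discordant pairs
  expect_equal(mcnemar_test(a, a)$p_value, 1)

  # asymptotic branch agrees with the standard implementation
  res2 <- mcnemar_test(a, b)
  tab <- table(a, b)
  ref <- stats::mcnemar.test(tab, correct = TRUE)
  expect_equal(res2$p_value, unname(ref$p.value), tolerance = 1e-10)
})
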