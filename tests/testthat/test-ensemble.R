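blobs_tbl <- function(n_per = 30, sep = 6, seed = 50) {
  set.seed(seed)
  tibble::tibble(
    label = rep(1:2, each = n_per),
    x1 = c(rnorm(n_per), rnorm(n_per, sep)),
    x2 = c(rnorm(n_per), rnorm(n_per, sep))
  )
}

xor_tbl <- function(n_per = 40, seed = 51) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(4, 4), c(0, 4), c(4, 0))
  lab <- rep(c(1, 1, 2, 2), each = n_per)
  tibble::tibble(
    label = lab,
    x1 = centers[rep(1:4, each = n_per), 1] + rnorm(4 * n_per, sd = 0.5),
    x2 = centers[rep(1:4, each = n_per), 2] + rnorm(4 * n_per, sd = 0.5)
  )
}

test_that("base learners fit separable data and record their architecture", {
  tbl <- blobs_tbl()
  learners <- train_base_learners(tbl, seed = 1)
  out <- predict_base_learners(learners, tbl)
  expect_equal(mean(out$lda$labels == as.character(tbl$label)), 1)
  expect_equal(learners$mlp$size, 15)
  expect_equal(learners$mlp$model$n[2], 15)  # hidden layer width

  for (o in out) {
    expect_true(all(abs(rowSums(o$posteriors) - 1) < 1e-9))
    expect_true(all(o$posteriors >= 0 & o$posteriors <= 1))
    amax <- learners$levels[max.col(o$posteriors, ties.method = "first")]
    expect_equal(amax, o$labels)
  }
})

test_that("RBF-SVM beats LDA on XOR-patterned classes", {
  tbl <- xor_tbl()
  learners <- train_base_learners(tbl, seed = 2)
  out <- predict_base_learners(learners, tbl)
  truth <- as.character(tbl$label)
  expect_gt(mean(out$svm$labels == truth), mean(out$lda$labels == truth))
})

test_that("learner training validates class structure", {
  tbl <- blobs_tbl()
  expect_error(train_base_learners(dplyr::filter(tbl, label == 1)),
               class = "kdemg_error_bad_input")
  one_row <- dplyr::bind_rows(dplyr::filter(tbl, label == 1),
                              dplyr::slice(dplyr::filter(tbl, label == 2), 1))
  expect_error(train_base_learners(one_row),
               class = "kdemg_error_stratification")
})

test_that("BKS cells take majority truth; unseen tuples fall back to posteriors", {
  fake_out <- function(labels, post) list(labels = labels, posteriors = post)
  lev <- c("a", "b")
  post_a <- matrix(c(0.9, 0.1), 4, 2, byrow = TRUE,
                   dimnames = list(NULL, lev))
  o1 <- fake_out(c("a", "a", "a", "b"), post_a)
  o2 <- fake_out(c("a", "a", "a", "b"), post_a)
  truth <- c("a", "a", "b", "b")
  bks <- bks_fit(list(o1, o2), truth)
  # tuple (a, a) saw truth {a, a, b}: majority a
  pred <- bks_predict(list(o1, o2), bks)
  expect_equal(pred[1:3], c("a", "a", "a"))
  expect_equal(pred[4], "b")

  # unseen tuple: mean-posterior fallback (here always "a")
  o3 <- fake_out(c("b", "a", "a", "a"), post_a)
  pred2 <- bks_predict(list(o3, o1), bks)
  expect_equal(pred2[1], "a")

  expect_error(bks_fit(list(o1, o2), character(0)),
               class = "kdemg_error_bad_input")
})

test_that("on training data BKS is at least as accurate as any single learner", {
  set.seed(52)
  tbl <- blobs_tbl(n_per = 60, sep = 2.2, seed = 53)  # overlapping classes
  learners <- train_base_learners(tbl, seed = 3)
  out <- predict_base_learners(learners, tbl)
  truth <- as.character(tbl$label)
  bks <- bks_fit(out, tbl$label)
  fused <- bks_predict(out, bks)
  single <- vapply(out, function(o) mean(o$labels == truth), numeric(1))
  expect_gte(mean(fused == truth), max(single))
})

test_that("with one base learner BKS reproduces that learner on seen tuples", {
  tbl <- blobs_tbl(n_per = 40, sep = 2, seed = 54)
  learners <- train_base_learners(tbl, seed = 4)
  out <- predict_base_learners(learners, tbl)["lda"]
  bks <- bks_fit(out, tbl$label)
  fused <- bks_predict(out, bks)
  # on the training rows every tuple is seen; majority truth for a single
  # learner's label cell is the Bayes response, which can only agree with or
  # improve on the learner -- equality holds where the cell is pure
  seen <- vapply(out[[1]]$labels, function(l) !is.null(bks$cells[[l]]),
                 logical(1))
  expect_true(all(seen))
  expect_gte(mean(fused == as.character(tbl$label)),
             mean(out[[1]]$labels == as.character(tbl$label)))
})

test_that("ensemble never predicts a class absent from training", {
  tbl <- blobs_tbl(n_per = 25, sep = 1.5, seed = 55)
  learners <- train_base_learners(tbl, seed = 5)
  out <- predict_base_learners(learners, tbl)
  bks <- bks_fit(out, tbl$label)
  fused <- bks_predict(out, bks)
  expect_true(all(fused %in% learners$levels))
})

test_that("boosted trees honour their configuration and are deterministic", {
  tbl <- blobs_tbl(n_per = 25, seed = 56)
  fit <- train_boosted_trees(tbl, n_estimators = 40, max_depth = 6, seed = 9)
  expect_equal(fit$params$max_depth, 6)
  expect_equal(fit$params$learning_rate, 0.1)
  d <- train_boosted_trees(tbl, seed = 9, n_estimators = 5)
  expect_equal(d$params$n_estimators, 5)

  defaults <- formals(train_boosted_trees)
  expect_equal(eval(defaults$n_estimators), 600L)
  expect_equal(eval(defaults$max_depth), 18L)
  expect_equal(eval(defaults$learning_rate), 0.1)

  p1 <- predict(fit, tbl)
  fit2 <- train_boosted_trees(tbl, n_estimators = 40, max_depth = 6, seed = 9)
  p2 <- predict(fit2, tbl)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$posteriors, p2$posteriors)

  expect_error(train_boosted_trees(dplyr::filter(tbl, label == 1)),
               class = "kdemg_error_bad_input")
})
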