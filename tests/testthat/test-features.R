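test_that("trimmed mean matches the sort-and-drop oracle", {
  expect_equal(trimmed_mean(rep(7, 13)), 7)
  expect_equal(trimmed_mean(1:20), 10.5)
  expect_equal(trimmed_mean(c(1:19, 1000)), 10.5)
  expect_equal(trimmed_mean(1:10, trim_spec(0, 0)), mean(1:10))
  expect_error(trimmed_mean(numeric(0)), class = "kdemg_error_empty_input")

  set.seed(30)
  for (i in 1:200) {
    n <- sample(c(1:19, 20:500), 1)
    x <- if (runif(1) < 0.3) sample(1:5, n, replace = TRUE) else rnorm(n)
    lo <- runif(1, 0, 30); hi <- runif(1, 0, 30)
    expect_identical(trimmed_mean(x, trim_spec(lo, hi)),
                     trimmed_mean_oracle(x, lo, hi))
  }
})

test_that("approximate entropy equals the definitional oracle", {
  expect_equal(approximate_entropy(rep(3, 50)), 0)

  set.seed(31)
  for (i in 1:10) {
    n <- sample(50:200, 1)
    x <- runif(n)
    m <- sample(1:2, 1)
    r_tol <- runif(1, 0.1, 0.3)
    got <- approximate_entropy(x, apen_params(m, r_tol))
    want <- apen_oracle(x, m, r_tol * sd(x))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("regular sequences have lower ApEn than their shuffles", {
  alternating <- rep(c(0, 1), 50)
  set.seed(32)
  shuffled <- sample(alternating)
  expect_lt(approximate_entropy(alternating),
            approximate_entropy(shuffled))
})

test_that("KDE features are deterministic, permutation invariant, composable", {
  set.seed(33)
  x <- rnorm(500)
  f1 <- kde_features(x)
  f2 <- kde_features(sample(x))
  expect_identical(f1, f2)
  expect_identical(f1, kde_features(x))
  expect_gte(f1[["tmavdd"]], 0)

  dens <- kde_diffusion(x, 512)
  expect_identical(f1[["tmd"]], trimmed_mean(dens$values, trim_spec()))
})

test_that("classic time features match their formulas", {
  expect_equal(classic_time_features(rep(-3, 10))[["rms"]], 3)
  expect_equal(classic_time_features(c(0, 1, 0, 1))[["wl"]], 3)
  expect_equal(classic_time_features(c(-1, 1, -1))[["mav"]], 1)
  set.seed(34)
  x <- rnorm(100)
  f <- classic_time_features(x)
  expect_equal(f[["rms"]], sqrt(mean(x^2)))
  expect_equal(f[["wl"]], sum(abs(diff(x))))
  expect_equal(f[["mav"]], mean(abs(x)))
})

test_that("sym4 energies conserve signal energy and match the filter-bank oracle", {
  expect_equal(dwt_energies(rep(0, 64)), rep(0, 4))

  set.seed(35)
  x <- rnorm(256)
  e <- dwt_energies(x)
  expect_equal(sum(e), sum(x^2), tolerance = 1e-6)

  impulse <- c(1, rep(0, 63))
  got <- dwt_energies(impulse)
  lo <- kdemg:::SYM4_LO
  hi <- kdemg:::SYM4_HI
  want <- dwt_energies_oracle(impulse, lo, hi)
  expect_equal(got, want, tolerance = 1e-10)

  for (i in 1:5) {
    x <- rnorm(128)
    expect_equal(dwt_energies(x), dwt_energies_oracle(x, lo, hi),
                 tolerance = 1e-10)
  }
  expect_error(dwt_energies(1:4), class = "kdemg_error_too_short")
})

test_that("feature tables have channel-major columns and drop bad rows", {
  set.seed(36)
  recs <- lapply(1:2, function(r) {
    emg_record(matrix(rnorm(12 * 1600), nrow = 12), fs = 2000,
               label = r, repetition = r)
  })
  tbl <- extract_feature_table(recs, "kde", window_spec(400, 300))
  feat_cols <- setdiff(names(tbl), c("subject", "label", "repetition",
                                     "window_id"))
  expect_length(feat_cols, 36)  # 12 channels x 3 density features
  expect_equal(feat_cols[1:3], c("ch01_tmd", "ch01_ed", "ch01_tmavdd"))
  expect_equal(nrow(tbl), 2 * (floor((1600 - 800) / 600) + 1))
  expect_true(all(is.finite(as.matrix(tbl[feat_cols]))))

  # a constant channel yields non-finite features; the row must be dropped
  bad <- recs
  bad[[1]]$samples[3, 1:800] <- 1
  expect_warning(
    tbl2 <- extract_feature_table(bad, "kde", window_spec(400, 300)),
    class = "kdemg_warning_dropped_rows"
  )
  expect_lt(nrow(tbl2), nrow(tbl))
})

test_that("per-channel TMD separates well-spaced synthetic classes", {
  cfg <- synthetic_config(n_classes = 2, n_channels = 4, n_repetitions = 6,
                          contraction_s = 1, amplitude_range = c(1, 6),
                          profile_seed = 37, noise_seed = 38)
  recs <- standardize_dataset(generate_dataset(cfg))
  tbl <- extract_feature_table(recs, "tmd", window_spec(400, 400))
  feats <- setdiff(names(tbl), c("subject", "label", "repetition",
                                 "window_id"))
  effect <- vapply(feats, function(f) {
    a <- tbl[[f]][tbl$label == 1]
    b <- tbl[[f]][tbl$label == 2]
    abs(mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
  }, numeric(1))
  expect_gt(max(effect), 1)
})

test_that("the ApEn tuner returns a parameter set from its grid", {
  set.seed(39)
  seqs <- lapply(1:4, function(i) cumsum(rnorm(120)))
  p <- tune_apen(seqs, n_boot = 8, seed = 5)
  expect_s3_class(p, "apen_params")
  expect_true(p$m %in% c(1L, 2L))
  expect_true(p$r_tol %in% c(0.1, 0.15, 0.2, 0.25))
  expect_identical(attr(tune_apen(seqs, n_boot = 8, seed = 5), "scores"),
                   attr(p, "scores"))
})
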