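make_sine <- function(freq, fs = 2000, dur = 2) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  emg_record(matrix(sin(2 * pi * freq * t), nrow = 1), fs = fs)
}

steady_amp <- function(rec) {
  # peak amplitude away from the filtfilt edges
  n <- n_samples(rec)
  max(abs(rec$samples[1, round(n * 0.25):round(n * 0.75)]))
}

test_that("band-pass rejects DC and the stop band, passes the pass band", {
  fs <- 2000
  const <- emg_record(matrix(5, nrow = 1, ncol = 2 * fs), fs = fs)
  out <- bandpass_filter(const, 20, 500, 4)
  expect_lt(steady_amp(out), 1e-6)

  passed <- bandpass_filter(make_sine(100), 20, 500, 4)
  expect_gte(steady_amp(passed), 0.95)
  expect_lte(steady_amp(passed), 1.05)

  stopped <- bandpass_filter(make_sine(5), 20, 500, 4)
  expect_lt(steady_amp(stopped), 0.05)
})

test_that("band-pass validates its band and warm-up length", {
  rec <- make_sine(100)
  expect_error(bandpass_filter(rec, 20, 1200, 4),
               class = "kdemg_error_invalid_band")
  expect_error(bandpass_filter(rec, 0, 500, 4),
               class = "kdemg_error_invalid_band")
  tiny <- emg_record(matrix(rnorm(5), nrow = 1), fs = 2000)
  expect_error(bandpass_filter(tiny, 20, 500, 4),
               class = "kdemg_error_too_short")
})

test_that("filtering is linear", {
  set.seed(11)
  rec <- emg_record(matrix(rnorm(4000), nrow = 1), fs = 2000)
  scaled <- rec
  scaled$samples <- 3.7 * rec$samples
  f1 <- bandpass_filter(rec, 20, 500, 4)
  f2 <- bandpass_filter(scaled, 20, 500, 4)
  expect_lt(max(abs(f2$samples - 3.7 * f1$samples)), 1e-10)
})

test_that("standardization gives zero mean, unit sample sd, and is idempotent", {
  rec <- emg_record(matrix(c(1, 2, 3), nrow = 1), fs = 10)
  out <- standardize_channels(rec)
  expect_equal(as.vector(out$samples), c(-1, 0, 1))

  set.seed(2)
  rec <- emg_record(matrix(rnorm(600, 4, 3), nrow = 2), fs = 10)
  out <- standardize_channels(rec)
  expect_lt(max(abs(rowMeans(out$samples))), 1e-12)
  expect_equal(unname(apply(out$samples, 1, sd)), c(1, 1))
  twice <- standardize_channels(out)
  expect_lt(max(abs(twice$samples - out$samples)), 1e-10)

  const <- emg_record(matrix(1, nrow = 1, ncol = 100), fs = 10)
  expect_error(standardize_channels(const),
               class = "kdemg_error_degenerate_channel")
})

test_that("pooled standardization preserves between-record amplitude ratios", {
  quiet <- emg_record(matrix(rnorm(1000, sd = 1), nrow = 1), fs = 100,
                      label = 1)
  loud <- emg_record(matrix(rnorm(1000, sd = 5), nrow = 1), fs = 100,
                     label = 2)
  out <- standardize_dataset(list(quiet, loud))
  ratio <- sd(out[[2]]$samples) / sd(out[[1]]$samples)
  expect_gt(ratio, 3)  # per-record standardization would force this to 1
})

test_that("3-sigma rule removes exactly the flagged samples", {
  set.seed(3)
  x <- rnorm(1000)
  x <- x[abs(x) < 2.9]  # force all inliers
  rec <- emg_record(matrix(x / sd(x), nrow = 1), fs = 100)
  out <- remove_outliers_3sigma(rec)
  expect_equal(out$removed[[1]], 0)
  expect_equal(out$channels[[1]], rec$samples[1, ])

  y <- c(rnorm(99), 10)
  rec <- emg_record(matrix(y, nrow = 1), fs = 100)
  out <- remove_outliers_3sigma(rec)
  expect_false(10 %in% out$channels[[1]])

  set.seed(4)
  z <- rnorm(10000)
  out <- remove_outliers_3sigma(emg_record(matrix(z, nrow = 1), fs = 100))
  frac <- out$removed[[1]] / 10000
  expect_gt(frac, 0.0027 - 0.002)
  expect_lt(frac, 0.0027 + 0.002)
})

test_that("window segmentation obeys the count formula", {
  rec <- emg_record(matrix(rnorm(20000), nrow = 2), fs = 2000)
  wins <- segment_windows(rec, window_spec(400, 300))
  expect_length(wins, 16)  # floor((10000 - 800) / 600) + 1
  expect_true(all(vapply(wins, n_samples, integer(1)) == 800))

  # property: exact count for assorted (T, W, S)
  set.seed(5)
  for (i in 1:25) {
    T_ <- sample(200:5000, 1)
    W <- sample(50:T_, 1)
    S <- sample(seq_len(W), 1)
    r <- emg_record(matrix(0, nrow = 1, ncol = T_), fs = 1000)
    wins <- segment_windows(r, window_spec(W, S))
    expect_length(wins, floor((T_ - W) / S) + 1)
  }

  whole <- segment_windows(rec, window_spec(5000, 5000))
  expect_length(whole, 1)
  short <- emg_record(matrix(0, nrow = 1, ncol = 100), fs = 2000)
  expect_error(segment_windows(short, window_spec(400, 300)),
               class = "kdemg_error_too_short")
})

test_that("middle third follows the floor boundary convention", {
  rec9 <- emg_record(matrix(1:9, nrow = 1), fs = 10)
  expect_equal(as.vector(middle_third(rec9)$samples), 4:6)
  rec10 <- emg_record(matrix(1:10, nrow = 1), fs = 10)
  expect_equal(as.vector(middle_third(rec10)$samples), 4:6)
  rec3 <- emg_record(matrix(1:3, nrow = 1), fs = 10)
  expect_equal(as.vector(middle_third(rec3)$samples), 2)
  rec2 <- emg_record(matrix(1:2, nrow = 1), fs = 10)
  expect_error(middle_third(rec2), class = "kdemg_error_too_short")

  for (n in c(3:12, 100, 101, 1000)) {
    rec <- emg_record(matrix(seq_len(n), nrow = 1), fs = 10)
    len <- n_samples(middle_third(rec))
    expect_true(len %in% c(floor(n / 3), floor(n / 3) + 1))
  }
})

test_that("records round-trip through CSV plus YAML sidecar", {
  dir <- withr::local_tempdir()
  rec <- emg_record(matrix(round(rnorm(60), 6), nrow = 3), fs = 1200,
                    label = 4, repetition = 2, subject = "s07")
  write_emg_csv(rec, file.path(dir, "a.csv"))
  back <- read_emg_csv(file.path(dir, "a.csv"))
  expect_equal(back$samples, rec$samples, ignore_attr = TRUE)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$label, rec$label)
  expect_equal(back$repetition, rec$repetition)
  expect_equal(back$subject, rec$subject)

  recs <- generate_dataset(tiny_config(n_repetitions = 2L,
                                       contraction_s = 0.5))
  write_emg_dataset(recs, file.path(dir, "ds"))
  back <- read_emg_dataset(file.path(dir, "ds"))
  expect_length(back, length(recs))
})
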