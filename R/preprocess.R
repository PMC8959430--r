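#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel with an order-`order` Butterworth band-pass applied
#' forward and backward (`signal::filtfilt`), so the output has no group
#' delay relative to the movement labels. Typical settings are 20--500 Hz at
#' order 4 for 2 ksps recordings and 5--500 Hz at order 8 for 1.2 ksps
#' recordings.
#'
#' @param record An [emg_record()].
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz < fs/2`.
#' @param order Filter order; an even integer `>= 2`. `signal::butter` is
#'   called with `order / 2` since band-pass design doubles the order.
#' @return The filtered record, same shape.
#' @examples
#' rec <- emg_record(matrix(rnorm(4000), nrow = 2), fs = 2000)
#' filt <- bandpass_filter(rec, 20, 500, order = 4)
#' @export
bandpass_filter <- function(record, low_hz = 20, high_hz = 500, order = 4L) {
  stopifnot_record(record)
  fs <- record$fs
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    abort(sprintf("Band edges must satisfy 0 < low < high < fs/2 = %g.", fs / 2),
          class = "kdemg_error_invalid_band")
  }
  if (order < 2 || order %% 2 != 0) {
    abort("`order` must be an even integer >= 2.",
          class = "kdemg_error_bad_input")
  }
  bf <- signal::butter(order / 2, c(low_hz, high_hz) / (fs / 2), type = "pass")
  pad <- 3 * (max(length(bf$a), length(bf$b)) - 1)
  if (ncol(record$samples) <= pad) {
    abort("Record shorter than the filter warm-up length.",
          class = "kdemg_error_too_short")
  }
  record$samples <- t(apply(record$samples, 1L, function(x) {
    signal::filtfilt(bf, x)
  }))
  record
}

#' Standardize channels to zero mean, unit standard deviation
#'
#' Per channel, subtracts the mean and divides by the sample standard
#' deviation (n - 1 denominator). Idempotent.
#'
#' @param record An [emg_record()].
#' @return The standardized record.
#' @export
standardize_channels <- function(record) {
  stopifnot_record(record)
  sds <- apply(record$samples, 1L, sd)
  if (any(!is.finite(sds)) || any(sds == 0)) {
    abort("Channel with zero variance cannot be standardized.",
          class = "kdemg_error_degenerate_channel")
  }
  record$samples <- (record$samples - rowMeans(record$samples)) / sds
  record
}

#' Remove outlying samples with the 3-sigma rule
#'
#' On a standardized record, drops samples whose absolute value exceeds three
#' channel standard deviations, in a single pass (the standard deviation is
#' not re-estimated after removal). Because channels may lose different
#' numbers of samples, the result is returned as a ragged per-channel list.
#'
#' @param record An [emg_record()], standardized.
#' @return An object of class `emg_channels`: a list with `channels` (list of
#'   numeric vectors), `fs`, `label`, `repetition`, `subject`, and
#'   `removed` (count per channel).
#' @export
remove_outliers_3sigma <- function(record) {
  stopifnot_record(record)
  out <- apply(record$samples, 1L, function(x) {
    keep <- abs(x) <= 3 * sd(x)
    x[keep]
  }, simplify = FALSE)
  removed <- ncol(record$samples) - lengths(out)
  if (any(removed > 0.5 * ncol(record$samples))) {
    warn("More than 50% of samples flagged as outliers on some channel.",
         class = "kdemg_warning_suspicious_signal")
  }
  structure(
    list(channels = out, fs = record$fs, label = record$label,
         repetition = record$repetition, subject = record$subject,
         removed = removed),
    class = "emg_channels"
  )
}

#' Standardize channels with statistics pooled over a session
#'
#' Applies the zero-mean/unit-sd transform per channel, but with the mean
#' and standard deviation pooled over all records of each subject -- as when
#' the continuous session recording is standardized before being segmented
#' into movements. Unlike per-record standardization this preserves the
#' relative amplitude of one movement against another, which carries class
#' information.
#'
#' @param records List of [emg_record()]s sharing channel count.
#' @return The records, standardized with per-subject pooled statistics.
#' @export
standardize_dataset <- function(records) {
  subjects <- vapply(records, function(r) r$subject, character(1))
  for (s in unique(subjects)) {
    idx <- which(subjects == s)
    pooled <- do.call(cbind, lapply(records[idx], function(r) r$samples))
    mu <- rowMeans(pooled)
    sigma <- apply(pooled, 1L, sd)
    if (any(!is.finite(sigma)) || any(sigma == 0)) {
      abort("Channel with zero pooled variance cannot be standardized.",
            class = "kdemg_error_degenerate_channel")
    }
    for (i in idx) {
      records[[i]]$samples <- (records[[i]]$samples - mu) / sigma
    }
  }
  records
}

#' Cut a record into analysis windows
#'
#' @param record An [emg_record()].
#' @param spec A [window_spec()].
#' @return A list of `emg_record` windows. Each window inherits the record's
#'   label, repetition and subject; the window start index (1-based sample)
#'   is stored in `meta$start`.
#' @examples
#' rec <- emg_record(matrix(rnorm(20000), nrow = 2), fs = 2000)
#' length(segment_windows(rec, window_spec(400, 300)))  # 16
#' @export
segment_windows <- function(record, spec) {
  stopifnot_record(record)
  n <- n_samples(record)
  if (spec$mode == "whole") {
    record$meta$start <- 1L
    return(list(record))
  }
  if (spec$mode == "middle_third") {
    return(list(middle_third(record)))
  }
  w <- round(spec$width_ms / 1000 * record$fs)
  s <- round(spec$step_ms / 1000 * record$fs)
  if (n < w) {
    abort("Record shorter than the window width.",
          class = "kdemg_error_too_short")
  }
  starts <- seq(1L, n - w + 1L, by = s)
  lapply(starts, function(i) {
    win <- record
    win$samples <- record$samples[, i:(i + w - 1L), drop = FALSE]
    win$meta$start <- i
    win
  })
}

#' Central third of a record
#'
#' Returns the samples at 1-based positions `floor(n/3) + 1` through
#' `floor(2n/3)`, the window over which densities are estimated in the
#' offline analysis (the onset and offset transients are excluded).
#'
#' @param record An [emg_record()] with at least 3 samples.
#' @return An `emg_record` covering the middle third.
#' @export
middle_third <- function(record) {
  stopifnot_record(record)
  n <- n_samples(record)
  if (n < 3) {
    abort("Need at least 3 samples for the middle third.",
          class = "kdemg_error_too_short")
  }
  idx <- (floor(n / 3) + 1L):floor(2 * n / 3)
  record$samples <- record$samples[, idx, drop = FALSE]
  record$meta$start <- idx[1L]
  record
}
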