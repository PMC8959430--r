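#' Labeled multi-channel sEMG segment
#'
#' An `emg_record` bundles a channels-by-time sample matrix with its sampling
#' rate and provenance: the movement class label (`0` denotes rest), the
#' repetition index within the acquisition session, and a subject identifier.
#' All pipeline stages consume and return this container.
#'
#' @param samples Numeric matrix, channels in rows, time samples in columns.
#'   A numeric vector is treated as a single channel.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param label Integer movement class id, `>= 0`; `0` means rest.
#' @param repetition Integer repetition index, `>= 1`.
#' @param subject Subject identifier string.
#' @param meta Named list of free-form annotations.
#'
#' @return An object of class `emg_record`.
#' @examples
#' rec <- emg_record(matrix(rnorm(400), nrow = 2), fs = 200,
#'                   label = 1, repetition = 1, subject = "s01")
#' n_channels(rec)
#' @export
emg_record <- function(samples, fs, label = 0L, repetition = 1L,
                       subject = "s01", meta = list()) {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, nrow = 1L)
  }
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort("`samples` must be a numeric matrix (channels x time).",
          class = "kdemg_error_bad_input")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a positive scalar (Hz).",
          class = "kdemg_error_bad_input")
  }
  if (label < 0) {
    abort("`label` must be >= 0 (0 = rest).", class = "kdemg_error_bad_input")
  }
  if (repetition < 1) {
    abort("`repetition` must be >= 1.", class = "kdemg_error_bad_input")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), label = as.integer(label),
         repetition = as.integer(repetition), subject = as.character(subject),
         meta = meta),
    class = "emg_record"
  )
}

#' @export
print.emg_record <- function(x, ...) {
  cat(sprintf(
    "<emg_record> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
    nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat(sprintf("  subject %s, label %d, repetition %d\n",
              x$subject, x$label, x$repetition))
  invisible(x)
}

#' @rdname emg_record
#' @param record,x An `emg_record`.
#' @export
n_channels <- function(record) nrow(record$samples)

#' @rdname emg_record
#' @export
n_samples <- function(record) ncol(record$samples)

#' @rdname emg_record
#' @param ... Passed on to methods.
#' @export
as_tibble.emg_record <- function(x, ...) {
  m <- x$samples
  tibble(
    time = rep((seq_len(ncol(m)) - 1) / x$fs, each = nrow(m)),
    channel = rep(seq_len(nrow(m)), times = ncol(m)),
    value = as.vector(m),
    label = x$label, repetition = x$repetition, subject = x$subject
  )
}

stopifnot_record <- function(record) {
  if (!inherits(record, "emg_record")) {
    abort("Expected an `emg_record`.", class = "kdemg_error_bad_input")
  }
}

#' Windowing specification
#'
#' Describes how a record is cut into analysis epochs. `sliding` mode produces
#' `floor((T - W) / S) + 1` windows of width `width_ms` every `step_ms`;
#' `middle_third` keeps the central third of the record; `whole` keeps the
#' record as a single window.
#'
#' @param width_ms Window width in milliseconds (ignored for `middle_third`
#'   and `whole`).
#' @param step_ms Step between window starts in milliseconds. For recordings
#'   described by their overlap, pass `width_ms - overlap_ms`.
#' @param mode One of `"sliding"`, `"middle_third"`, `"whole"`.
#' @return A `window_spec` object.
#' @examples
#' window_spec(400, 300)                  # 400 ms windows, 100 ms overlap
#' window_spec(160, 40)                   # 160 ms windows, 40 ms increment
#' window_spec(mode = "middle_third")
#' @export
window_spec <- function(width_ms = 400, step_ms = width_ms,
                        mode = c("sliding", "middle_third", "whole")) {
  mode <- match.arg(mode)
  if (mode == "sliding") {
    if (width_ms <= 0 || step_ms <= 0) {
      abort("`width_ms` and `step_ms` must be positive.",
            class = "kdemg_error_bad_input")
    }
    if (step_ms > width_ms) {
      abort("`step_ms` must not exceed `width_ms` in sliding mode.",
            class = "kdemg_error_bad_input")
    }
  }
  structure(list(width_ms = width_ms, step_ms = step_ms, mode = mode),
            class = "window_spec")
}
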