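#' Configuration for the synthetic sEMG generator
#'
#' Defaults emulate a conventional-control acquisition protocol: 2 ksps
#' sampling, 5 s contractions separated by 3 s rest, 6 repetitions per
#' movement, EMG-like band-limited noise in 20--450 Hz, and a 20 dB
#' per-channel signal-to-noise ratio. Class structure (per-class per-channel
#' amplitude profiles and spectral shape) is drawn once from `profile_seed`;
#' signal realizations are drawn from `noise_seed`, so classes can be held
#' fixed while resampling noise.
#'
#' @param n_subjects Number of subjects.
#' @param n_classes Number of movement classes (excluding rest).
#' @param n_channels Number of sEMG channels.
#' @param n_repetitions Repetitions per movement, `>= 2`.
#' @param fs Sampling rate (Hz).
#' @param contraction_s Contraction duration (s).
#' @param rest_s Rest duration between contractions (s); kept for protocol
#'   realism and used when `include_rest = TRUE`.
#' @param band Two-element vector, EMG energy band (Hz), inside `(0, fs/2)`.
#' @param snr_db Per-channel SNR of the contraction plateau over the additive
#'   white sensor noise, in dB.
#' @param amplitude_range Range the per-class per-channel plateau amplitudes
#'   are drawn from.
#' @param ramp_fraction Fraction of the contraction spent ramping up (and
#'   down) in the trapezoidal envelope.
#' @param profile_seed,noise_seed Independent integer seed streams.
#' @param include_rest Also emit rest records (label 0), one per repetition.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_subjects = 1L, n_classes = 10L,
                             n_channels = 8L, n_repetitions = 6L,
                             fs = 2000, contraction_s = 5, rest_s = 3,
                             band = c(20, 450), snr_db = 20,
                             amplitude_range = c(1, 4),
                             ramp_fraction = 0.1,
                             profile_seed = 101L, noise_seed = 202L,
                             include_rest = FALSE) {
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2)) {
    abort("`band` must lie inside (0, fs/2).", class = "kdemg_error_config")
  }
  if (n_repetitions < 2 || n_classes < 1 || n_channels < 1 || n_subjects < 1) {
    abort("Counts must be positive (and repetitions >= 2).",
          class = "kdemg_error_config")
  }
  structure(as.list(environment()), class = "synthetic_config")
}

trapezoid_envelope <- function(n, ramp_fraction) {
  r <- max(1L, round(n * ramp_fraction))
  env <- rep(1, n)
  env[1:r] <- seq(0, 1, length.out = r)
  env[(n - r + 1):n] <- seq(1, 0, length.out = r)
  env
}

# Band-limited unit-variance noise: white Gaussian noise filtered into the
# class's sub-band with a 4th-order Butterworth band-pass.
shaped_noise <- function(n, fs, band, bf = NULL) {
  x <- rnorm(n + 2000)  # pad to discard filter transients
  bf <- bf %||% signal::butter(2, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)[1001:(1000 + n)]
  y / sd(y)
}

draw_class_profiles <- function(config) {
  set.seed(config$profile_seed)
  lapply(seq_len(config$n_classes), function(cl) {
    list(
      amplitude = runif(config$n_channels, config$amplitude_range[1],
                        config$amplitude_range[2]),
      band = c(runif(1, config$band[1], config$band[1] + 40),
               runif(1, max(config$band[2] - 150, config$band[1] + 80),
                     config$band[2]))
    )
  })
}

synth_record <- function(profile, config, label, rep_i, subject, mix = NULL) {
  n <- round(config$contraction_s * config$fs)
  env <- trapezoid_envelope(n, config$ramp_fraction)
  noise_sd <- 10^(-config$snr_db / 20)
  bf <- signal::butter(2, profile$band / (config$fs / 2), type = "pass")
  samples <- t(vapply(seq_len(config$n_channels), function(ch) {
    s <- profile$amplitude[ch] * env * shaped_noise(n, config$fs,
                                                    profile$band, bf)
    if (!is.null(mix)) {
      bf2 <- signal::butter(2, mix$profile$band / (config$fs / 2),
                            type = "pass")
      s <- s + mix$coef * mix$profile$amplitude[ch] * env *
        shaped_noise(n, config$fs, mix$profile$band, bf2)
    }
    s + rnorm(n, sd = noise_sd * max(profile$amplitude[ch], 1))
  }, numeric(n)))
  emg_record(samples, fs = config$fs, label = label, repetition = rep_i,
             subject = subject)
}

rest_record <- function(config, rep_i, subject) {
  n <- round(config$rest_s * config$fs)
  noise_sd <- 10^(-config$snr_db / 20) * mean(config$amplitude_range)
  samples <- matrix(rnorm(config$n_channels * n, sd = noise_sd),
                    nrow = config$n_channels)
  emg_record(samples, fs = config$fs, label = 0L, repetition = rep_i,
             subject = subject)
}

#' Generate a synthetic single-movement dataset
#'
#' Each class owns a per-channel plateau amplitude vector and a spectral
#' sub-band, both drawn once from the profile seed. Each repetition is
#' amplitude-modulated band-limited Gaussian noise under a trapezoidal
#' onset/offset envelope plus white sensor noise at the configured SNR.
#' Identical seeds give bit-identical datasets.
#'
#' @param config A [synthetic_config()].
#' @return List of [emg_record()]s, ordered subject-class-repetition.
#' @examples
#' recs <- generate_dataset(synthetic_config(n_classes = 2, n_repetitions = 2,
#'                                           contraction_s = 1))
#' length(recs)  # 4
#' @export
generate_dataset <- function(config = synthetic_config()) {
  profiles <- draw_class_profiles(config)
  set.seed(config$noise_seed)
  records <- list()
  for (s in seq_len(config$n_subjects)) {
    subject <- sprintf("s%02d", s)
    for (cl in seq_len(config$n_classes)) {
      for (r in seq_len(config$n_repetitions)) {
        records[[length(records) + 1L]] <-
          synth_record(profiles[[cl]], config, cl, r, subject)
        if (config$include_rest) {
          records[[length(records) + 1L]] <- rest_record(config, r, subject)
        }
      }
    }
  }
  records
}

#' Generate a synthetic simultaneous-movement dataset
#'
#' Emulates a two-degree-of-freedom wrist protocol: four single movements
#' (flexion, extension, pronation, supination), the four valid two-movement
#' combinations (flexion/extension paired with pronation/supination), and
#' rest -- nine classes. Combination classes superpose the two component
#' channel profiles (independent realizations, mixing coefficient
#' `mix_coef`), so combined-class channel power is approximately the sum of
#' the component powers. Defaults: 8 channels at 1.2 ksps, four 3 s
#' repetitions per class.
#'
#' @param config A [synthetic_config()]; `n_channels` must be 8 and `fs`
#'   1200 (protocol invariants), `n_classes` is fixed at 4 single movements.
#' @param mix_coef Weight of each component in combined classes.
#' @return List of [emg_record()]s with labels 0 (rest), 1--4 (singles),
#'   5--8 (combinations).
#' @export
generate_simultaneous_dataset <- function(config = synthetic_config(
                                            n_classes = 4L, n_channels = 8L,
                                            n_repetitions = 4L, fs = 1200,
                                            contraction_s = 3, rest_s = 3,
                                            band = c(20, 450)),
                                          mix_coef = 1) {
  if (config$n_channels != 8L || config$fs != 1200) {
    abort("The simultaneous protocol uses 8 channels at 1200 Hz.",
          class = "kdemg_error_config")
  }
  config$n_classes <- 4L
  profiles <- draw_class_profiles(config)
  combos <- list(c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L))
  set.seed(config$noise_seed)
  records <- list()
  for (s in seq_len(config$n_subjects)) {
    subject <- sprintf("s%02d", s)
    for (r in seq_len(config$n_repetitions)) {
      records[[length(records) + 1L]] <- rest_record(config, r, subject)
      for (cl in 1:4) {
        records[[length(records) + 1L]] <-
          synth_record(profiles[[cl]], config, cl, r, subject)
      }
      for (ci in seq_along(combos)) {
        cmb <- combos[[ci]]
        records[[length(records) + 1L]] <- synth_record(
          profiles[[cmb[1]]], config, 4L + ci, r, subject,
          mix = list(profile = profiles[[cmb[2]]], coef = mix_coef))
      }
    }
  }
  records
}
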