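#' Symmetric trimming specification
#'
#' Fraction of observations dropped from each tail before averaging. The
#' default removes 5% of the data in the low range and 5% in the high range.
#'
#' @param lower_pct,upper_pct Percentages in `[0, 50)`.
#' @return A `trim_spec` object.
#' @export
trim_spec <- function(lower_pct = 5, upper_pct = 5) {
  if (lower_pct < 0 || lower_pct >= 50 || upper_pct < 0 || upper_pct >= 50) {
    abort("Trim percentages must lie in [0, 50).",
          class = "kdemg_error_bad_input")
  }
  structure(list(lower_pct = lower_pct, upper_pct = upper_pct),
            class = "trim_spec")
}

#' Approximate-entropy parameters
#'
#' @param m Embedding dimension, integer `>= 1`; default 2.
#' @param r_tol Tolerance as a multiple of the sequence standard deviation;
#'   default 0.2.
#' @return An `apen_params` object.
#' @export
apen_params <- function(m = 2L, r_tol = 0.2) {
  if (m < 1 || r_tol <= 0) {
    abort("Need m >= 1 and r_tol > 0.", class = "kdemg_error_bad_input")
  }
  structure(list(m = as.integer(m), r_tol = r_tol), class = "apen_params")
}

#' Trimmed mean
#'
#' Sorts the values, drops `floor(lower_pct/100 * n)` smallest and
#' `floor(upper_pct/100 * n)` largest observations, and averages the rest.
#' Count-based trimming keeps the operation exact and deterministic under
#' ties.
#'
#' @param values Numeric vector with at least one finite value.
#' @param spec A [trim_spec()].
#' @return The trimmed mean (scalar).
#' @examples
#' trimmed_mean(1:20, trim_spec(5, 5))  # drops 1 and 20 -> 10.5
#' @export
trimmed_mean <- function(values, spec = trim_spec()) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0) {
    abort("Empty input to trimmed_mean().", class = "kdemg_error_empty_input")
  }
  lo <- floor(spec$lower_pct / 100 * n)
  hi <- floor(spec$upper_pct / 100 * n)
  s <- sort(values)
  mean(s[(lo + 1):(n - hi)])
}

#' Approximate entropy
#'
#' Regularity statistic `ApEn(m, r) = Phi_m(r) - Phi_(m+1)(r)` computed with
#' Chebyshev distance and self-matches included. The tolerance is resolved as
#' `r_tol * sd(seq)`; the smaller the ApEn, the more regular (less complex)
#' the sequence. Constant sequences return 0.
#'
#' @param seq Numeric vector, length `>= m + 2`.
#' @param params An [apen_params()].
#' @return ApEn value (scalar, `>= 0` up to floating point).
#' @examples
#' approximate_entropy(sin(1:100), apen_params(2, 0.2))
#' @export
approximate_entropy <- function(seq, params = apen_params()) {
  if (length(seq) < params$m + 2) {
    abort("Sequence too short for the requested embedding dimension.",
          class = "kdemg_error_too_short")
  }
  s <- sd(seq)
  if (!is.finite(s) || s == 0) return(0)
  .apen_cpp(as.numeric(seq), params$m, params$r_tol * s)
}

#' KDE features of one channel-window
#'
#' Estimates the sample density of a window's channel once with
#' [kde_diffusion()] and derives the three density features from it:
#'
#' * **TMD** -- trimmed mean of the density values on the grid;
#' * **ED** -- approximate entropy of the density value sequence (ordered by
#'   abscissa);
#' * **TMAVDD** -- trimmed mean of the absolute first Hermite-kernel density
#'   derivative evaluated on the same grid, reusing the diffusion bandwidth.
#'
#' @param channel Numeric vector of (standardized) channel samples.
#' @param trim A [trim_spec()]; applied identically to TMD and TMAVDD.
#' @param apen An [apen_params()].
#' @param n_grid Density grid resolution; default 512 so the entropy of the
#'   density sequence stays inexpensive per window.
#' @return Named numeric vector `c(tmd, ed, tmavdd)`.
#' @export
kde_features <- function(channel, trim = trim_spec(), apen = apen_params(),
                         n_grid = 512L) {
  dens <- kde_diffusion(channel, n_grid = n_grid)
  deriv <- kde_derivative_hermite(channel, h = dens$bandwidth, r = 1L,
                                  eval_points = dens$grid)
  c(tmd = trimmed_mean(dens$values, trim),
    ed = approximate_entropy(dens$values, apen),
    tmavdd = trimmed_mean(abs(deriv$values), trim))
}

#' Classic time-domain features
#'
#' Root mean square, waveform length, and mean absolute value of a channel.
#'
#' @param channel Numeric vector, length `>= 2`.
#' @return Named numeric vector `c(rms, wl, mav)`.
#' @examples
#' classic_time_features(c(0, 1, 0, 1))
#' @export
classic_time_features <- function(channel) {
  if (length(channel) < 2) {
    abort("Need at least 2 samples.", class = "kdemg_error_too_short")
  }
  c(rms = sqrt(mean(channel^2)),
    wl = sum(abs(diff(channel))),
    mav = mean(abs(channel)))
}

#' Assemble a feature table from records
#'
#' Windows each record, computes per-channel features, and stacks them into a
#' tibble with one row per window. Column names encode channel and feature
#' (`ch01_tmd`, `ch01_ed`, ...), channel-major, so 12 channels with the KDE
#' set give a 36-dimensional feature vector. Rows with any non-finite feature
#' are dropped (and counted in the `dropped` attribute), never imputed.
#'
#' Outlier removal (3-sigma rule) is applied per channel-window before
#' density estimation when `remove_outliers = TRUE`.
#'
#' @param records List of [emg_record()]s sharing channel count and `fs`.
#' @param feature_set `"kde"`, `"classic"`, `"dwt"`, or `"all"`; `"tmd"`
#'   computes the trimmed mean of density only (used by the online driver).
#' @param window A [window_spec()].
#' @param trim A [trim_spec()].
#' @param apen An [apen_params()].
#' @param n_grid Density grid resolution for the KDE features.
#' @param remove_outliers Drop 3-sigma outlying samples per channel-window
#'   before density estimation.
#' @return A tibble: `subject`, `label`, `repetition`, `window_id`, then one
#'   column per channel x feature.
#' @export
extract_feature_table <- function(records,
                                  feature_set = c("kde", "classic", "dwt",
                                                  "all", "tmd"),
                                  window = window_spec(400, 300),
                                  trim = trim_spec(),
                                  apen = apen_params(),
                                  n_grid = 512L,
                                  remove_outliers = TRUE) {
  feature_set <- match.arg(feature_set)
  nch <- unique(vapply(records, n_channels, integer(1)))
  fs <- unique(vapply(records, function(r) r$fs, numeric(1)))
  if (length(nch) != 1L || length(fs) != 1L) {
    abort("All records must share channel count and sampling rate.",
          class = "kdemg_error_schema")
  }
  rows <- purrr::map(records, function(rec) {
    wins <- segment_windows(rec, window)
    purrr::imap(wins, function(win, wi) {
      feats <- purrr::map(seq_len(nch), function(ch) {
        x <- win$samples[ch, ]
        if (remove_outliers) x <- x[abs(x) <= 3 * sd(x)]
        # a degenerate channel marks the whole row for removal
        tryCatch(channel_features(x, feature_set, trim, apen, n_grid, fs),
                 error = function(e) {
                   nm <- feature_names(feature_set)
                   setNames(rep(NaN, length(nm)), nm)
                 })
      })
      nm <- purrr::imap(feats, function(f, ch) {
        sprintf("ch%02d_%s", ch, names(f))
      })
      vals <- unlist(feats, use.names = FALSE)
      names(vals) <- unlist(nm)
      dplyr::bind_cols(
        tibble(subject = rec$subject, label = rec$label,
               repetition = rec$repetition,
               window_id = win$meta$start %||% wi),
        as_tibble(as.list(vals))
      )
    })
  })
  tbl <- dplyr::bind_rows(unlist(rows, recursive = FALSE))
  feat_cols <- setdiff(names(tbl), c("subject", "label", "repetition",
                                     "window_id"))
  finite <- apply(as.matrix(tbl[feat_cols]), 1L, function(r) all(is.finite(r)))
  if (any(!finite)) {
    warn(sprintf("Dropped %d window(s) with non-finite features.", sum(!finite)),
         class = "kdemg_warning_dropped_rows")
  }
  out <- tbl[finite, , drop = FALSE]
  attr(out, "dropped") <- sum(!finite)
  attr(out, "feature_set") <- feature_set
  out
}

feature_names <- function(feature_set) {
  switch(feature_set,
         kde = c("tmd", "ed", "tmavdd"),
         tmd = "tmd",
         classic = c("rms", "wl", "mav"),
         dwt = c("d1", "d2", "d3", "a3"),
         all = c("tmd", "ed", "tmavdd", "rms", "wl", "mav",
                 "d1", "d2", "d3", "a3"))
}

channel_features <- function(x, feature_set, trim, apen, n_grid, fs) {
  switch(
    feature_set,
    kde = kde_features(x, trim, apen, n_grid),
    tmd = {
      dens <- kde_diffusion(x, n_grid = n_grid)
      c(tmd = trimmed_mean(dens$values, trim))
    },
    classic = classic_time_features(x),
    dwt = {
      e <- dwt_energies(x)
      names(e) <- c("d1", "d2", "d3", "a3")
      e
    },
    all = {
      e <- dwt_energies(x)
      names(e) <- c("d1", "d2", "d3", "a3")
      c(kde_features(x, trim, apen, n_grid), classic_time_features(x), e)
    }
  )
}

#' Coarse ApEn parameter tuner
#'
#' Grid search over `m` and `r_tol` selecting the setting whose ApEn is most
#' stable across bootstrap halves of the supplied sequences (smallest mean
#' absolute half-vs-half difference relative to its mean value). A stand-in
#' for heuristic tolerance tuning when no tuned values are available;
#' per-subject application is intended.
#'
#' @param sequences List of numeric vectors (e.g. density value sequences
#'   from one subject).
#' @param m_grid Candidate embedding dimensions.
#' @param r_grid Candidate tolerance multiples.
#' @param n_boot Bootstrap replicates per setting.
#' @param seed Integer seed for the bootstrap.
#' @return The selected [apen_params()], with the score table in attribute
#'   `"scores"`.
#' @export
tune_apen <- function(sequences, m_grid = c(1L, 2L),
                      r_grid = c(0.1, 0.15, 0.2, 0.25),
                      n_boot = 20L, seed = 1L) {
  grid <- expand.grid(m = m_grid, r_tol = r_grid)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  scores <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    p <- apen_params(grid$m[i], grid$r_tol[i])
    diffs <- purrr::map_dbl(seq_len(n_boot), function(b) {
      s <- sequences[[sample.int(length(sequences), 1L)]]
      idx <- sample.int(length(s))
      half <- floor(length(s) / 2)
      a1 <- approximate_entropy(s[sort(idx[1:half])], p)
      a2 <- approximate_entropy(s[sort(idx[(half + 1):(2 * half)])], p)
      abs(a1 - a2) / max(mean(c(a1, a2)), 1e-12)
    })
    mean(diffs)
  })
  best <- which.min(scores)
  out <- apen_params(grid$m[best], grid$r_tol[best])
  attr(out, "scores") <- cbind(grid, instability = scores)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
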