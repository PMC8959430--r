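# Independent reference implementations used to check the package's fast
# paths. Deliberately written the "slow, obvious" way.

# Definitional approximate entropy: explicit embedding matrix, explicit
# Chebyshev distances, self-matches included.
apen_oracle <- function(x, m, r) {
  phi <- function(mm) {
    n <- length(x) - mm + 1
    X <- sapply(seq_len(mm), function(k) x[k:(k + n - 1)])
    X <- matrix(X, nrow = n)
    C <- vapply(seq_len(n), function(i) {
      d <- apply(abs(X - matrix(X[i, ], n, mm, byrow = TRUE)), 1L, max)
      mean(d <= r)
    }, numeric(1))
    mean(log(C))
  }
  phi(m) - phi(m + 1)
}

# Sort-and-drop trimmed mean.
trimmed_mean_oracle <- function(x, lower_pct, upper_pct) {
  x <- sort(x)
  n <- length(x)
  lo <- floor(lower_pct / 100 * n)
  hi <- floor(upper_pct / 100 * n)
  mean(x[(lo + 1):(n - hi)])
}

# Periodized DWT analysis step as an explicit transform matrix: row k is the
# filter circularly placed at offset 2k. An independent route to the same
# subband coefficients as the recursive implementation.
dwt_step_oracle <- function(x, filt) {
  n <- length(x)
  W <- matrix(0, n / 2, n)
  for (k in seq_len(n / 2)) {
    for (m in seq_along(filt)) {
      W[k, (2 * (k - 1) + m - 1) %% n + 1] <-
        W[k, (2 * (k - 1) + m - 1) %% n + 1] + filt[m]
    }
  }
  drop(W %*% x)
}

dwt_energies_oracle <- function(x, lo, hi) {
  a <- x
  energies <- numeric(3)
  for (lev in 1:3) {
    d <- dwt_step_oracle(a, hi)
    a <- dwt_step_oracle(a, lo)
    energies[lev] <- sum(d^2)
  }
  c(energies, sum(a^2))
}

# Exhaustive CFS optimum over all non-empty subsets.
exhaustive_cfs <- function(corr) {
  p <- length(corr$feature_class)
  best <- NULL
  best_m <- -Inf
  for (k in seq_len(p)) {
    sets <- utils::combn(p, k)
    for (j in seq_len(ncol(sets))) {
      m <- cfs_merit(sets[, j], corr)
      if (m > best_m + 1e-12) {
        best_m <- m
        best <- sets[, j]
      }
    }
  }
  list(subset = best, merit = best_m)
}

# Synthetic correlation structure with low feature-feature redundancy.
random_corr <- function(p, seed) {
  set.seed(seed)
  rcf <- runif(p, 0.1, 0.9)
  rff <- matrix(runif(p * p, 0, 0.15), p)
  rff[lower.tri(rff)] <- t(rff)[lower.tri(rff)]
  diag(rff) <- 1
  names(rcf) <- sprintf("f%02d", seq_len(p))
  dimnames(rff) <- list(names(rcf), names(rcf))
  structure(list(feature_class = rcf, feature_feature = rff,
                 measure = "synthetic"),
            class = "kdemg_correlations")
}

# Definitional Fleiss kappa (no algebraic shortcuts).
fleiss_oracle <- function(ratings) {
  N <- nrow(ratings)
  n <- sum(ratings[1, ])
  pj <- colSums(ratings) / (N * n)
  Pi <- numeric(N)
  for (i in seq_len(N)) {
    s <- 0
    for (j in seq_len(ncol(ratings))) {
      s <- s + ratings[i, j] * (ratings[i, j] - 1)
    }
    Pi[i] <- s / (n * (n - 1))
  }
  (mean(Pi) - sum(pj^2)) / (1 - sum(pj^2))
}

# Seeded random confusion matrix with guaranteed positive total.
random_cm <- function(c_, seed) {
  set.seed(seed)
  m <- matrix(rpois(c_ * c_, sample(1:20, 1)), c_, c_)
  structure(m, class = "kdemg_confusion",
            dimnames = list(truth = as.character(seq_len(c_)),
                            predicted = as.character(seq_len(c_))))
}

# Small, fast synthetic configs for pipeline-level tests.
tiny_config <- function(...) {
  args <- list(n_classes = 3L, n_channels = 3L, n_repetitions = 6L,
               fs = 2000, contraction_s = 2)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

trapezoid_integral <- function(grid, values) {
  sum(diff(grid) * (head(values, -1) + tail(values, -1)) / 2)
}
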