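# Symlet-4 analysis filters (8-tap least-asymmetric orthogonal pair,
# normalized so the low-pass sums to sqrt(2)). Frozen to full double
# precision; the pair satisfies the conjugate-quadrature conditions, so the
# periodized transform below is exactly orthonormal.
SYM4_LO <- c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
             0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
             -0.012603967262037833, 0.0322231006040427)
SYM4_HI <- c(-0.0322231006040427, -0.012603967262037833, 0.09921954357684722,
             0.29785779560527736, -0.8037387518059161, 0.49761866763201545,
             0.02963552764599851, -0.07576571478927333)

# One periodized analysis step: circular correlation with the filter, then
# keep every second output. Requires even length.
dwt_step <- function(x, filt) {
  n <- length(x)
  L <- length(filt)
  idx <- outer(seq(0, n - 2, by = 2), seq_len(L) - 1L, "+") %% n + 1L
  drop(matrix(x[idx], ncol = L) %*% filt)
}

#' Wavelet energy features (3-level sym4 decomposition)
#'
#' Decomposes a channel with a 3-level periodized orthogonal discrete wavelet
#' transform using the sym4 mother wavelet and returns the energies (sums of
#' squared coefficients) of the detail bands D1, D2, D3 and the approximation
#' A3. With periodization and an orthogonal wavelet the four energies sum
#' exactly to the signal energy.
#'
#' @param channel Numeric vector; length must be at least 8 and is padded by
#'   symmetric wrap to a multiple of 8 if needed.
#' @return Numeric vector `c(D1, D2, D3, A3)` of band energies.
#' @examples
#' x <- rnorm(256)
#' sum(dwt_energies(x)) - sum(x^2)   # ~ 0
#' @export
dwt_energies <- function(channel) {
  if (length(channel) < 8) {
    abort("Channel too short for a 3-level sym4 decomposition.",
          class = "kdemg_error_too_short")
  }
  # pad to a multiple of 2^3 by circular extension so each level stays even
  rem <- length(channel) %% 8
  if (rem != 0) channel <- c(channel, channel[seq_len(8 - rem)])
  a <- channel
  energies <- numeric(3)
  for (lev in 1:3) {
    d <- dwt_step(a, SYM4_HI)
    a <- dwt_step(a, SYM4_LO)
    energies[lev] <- sum(d^2)
  }
  c(energies, sum(a^2))
}
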