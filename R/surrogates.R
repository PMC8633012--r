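#' Fourier-transform (FT) phase-randomized surrogate
#'
#' Returns a series with exactly the same amplitude spectrum as the input but
#' independently uniform random phases at every positive-frequency bin
#' (conjugate-symmetric, so the output is real). The DC bin — and, for
#' even-length input, the Nyquist bin — is left untouched, so the mean and
#' total energy (hence variance) of the input are preserved exactly, as is
#' the full sample autocovariance (Wiener-Khinchin). The sample histogram is
#' \emph{not} preserved: FT surrogates of a strictly positive power series
#' routinely take negative values.
#'
#' @param series real numeric vector, length >= 4.
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (draws advance the global RNG).
#' @return numeric vector of the same length.
#' @seealso [iaaft_phase_randomize()] for the histogram-preserving variant.
#' @export
ft_phase_randomize <- function(series, seed = NULL) {
  stopifnot(is.numeric(series), length(series) >= 4)
  m <- length(series)
  X <- stats::fft(series)
  half <- (m - 1) %/% 2             # number of free positive-frequency bins
  draw <- function() stats::runif(half, 0, 2 * pi)
  theta <- if (is.null(seed)) draw() else with_seed(seed, draw())
  rot <- exp(1i * theta)
  X[2:(half + 1)] <- Mod(X[2:(half + 1)]) * rot
  X[m:(m - half + 1)] <- Conj(X[2:(half + 1)])
  Re(stats::fft(X, inverse = TRUE)) / m
}

#' Iterated amplitude-adjusted Fourier transform (IAAFT) surrogate
#'
#' Produces a surrogate that is an exact permutation of the input's values
#' (the sample histogram is preserved exactly) whose amplitude spectrum
#' approximates the input's. Iterates the classic two-step scheme — impose
#' the target amplitude spectrum, then restore the sorted sample values by
#' rank — until the rank order stabilizes or `max_iter` is reached.
#'
#' @param series real numeric vector, length >= 4.
#' @param max_iter maximum number of iterations (default 100).
#' @param seed optional integer seed for the initial shuffle.
#' @return numeric vector with attributes `converged` (logical), `iterations`
#'   (count used) and `spectral_error` (relative amplitude-spectrum error per
#'   iteration).
#' @export
iaaft_phase_randomize <- function(series, max_iter = 100, seed = NULL) {
  stopifnot(is.numeric(series), length(series) >= 4, max_iter >= 1)
  m <- length(series)
  amp <- Mod(stats::fft(series))
  sx <- sort(series)
  shuffle <- function() sample.int(m)
  perm <- if (is.null(seed)) shuffle() else with_seed(seed, shuffle())
  y <- series[perm]
  anorm <- sqrt(sum(amp^2))
  errs <- numeric(0)
  prev_rank <- integer(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Y <- stats::fft(y)
    # spectrum step: keep phases, impose target amplitudes
    phase <- Y / ifelse(Mod(Y) == 0, 1, Mod(Y))
    z <- Re(stats::fft(amp * phase, inverse = TRUE)) / m
    # amplitude step: restore exact sample values by rank
    rk <- rank(z, ties.method = "first")
    y <- sx[rk]
    errs <- c(errs, sqrt(sum((Mod(stats::fft(y)) - amp)^2)) / anorm)
    if (length(prev_rank) && all(rk == prev_rank)) { converged <- TRUE; break }
    prev_rank <- rk
  }
  structure(y, converged = converged, iterations = it, spectral_error = errs)
}

# Vectorized FT phase randomization of the columns of a real matrix, given
# the precomputed column FFTs. One fresh uniform phase per positive-frequency
# bin per column; DC (and Nyquist, for even length) rows untouched. Used by
# the intra-scale null Monte Carlo, where the same amplitude spectra are
# re-randomized H times.
ft_randomize_columns <- function(F, m) {
  half <- (m - 1) %/% 2
  u <- ncol(F)
  theta <- matrix(stats::runif(half * u, 0, 2 * pi), half, u)
  G <- F
  G[2:(half + 1), ] <- Mod(F[2:(half + 1), , drop = FALSE]) * exp(1i * theta)
  G[m:(m - half + 1), ] <- Conj(G[2:(half + 1), , drop = FALSE])
  Re(stats::mvfft(G, inverse = TRUE)) / m
}
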