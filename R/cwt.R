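#' Continuous wavelet transform with a generalized Morse wavelet
#'
#' Decomposes a signal over a logarithmic grid of scales using the analytic
#' generalized Morse wavelet (see [morse_params()]). The transform is computed
#' in the frequency domain: the signal is zero-padded to the next power of
#' two, Fourier transformed once, multiplied by each scale's frequency
#' response and inverse transformed. Padding only contaminates coefficients
#' outside the cone of influence, which downstream filtering discards.
#'
#' By default the centre-frequency grid runs from the Nyquist frequency down
#' to the frequency whose edge-effect half-width reaches the middle of the
#' signal, at `voices_per_octave` scales per octave. The per-scale amplitude
#' normalization is immaterial for inter-scale power correlations (Pearson
#' correlation is invariant to positive rescaling of either series); the
#' implementation uses the peak-normalized frequency response, so a unit
#' sinusoid yields the same peak power at every scale.
#'
#' @param sig an [ispc_signal], preprocessed (finite, ideally zero-meaned).
#' @param params a [morse_params()] object.
#' @return an object of class `ispc_cwt` with fields:
#'   \describe{
#'     \item{coeffs}{complex matrix, `u` scales x `n` times; row 1 is the
#'       highest-frequency scale.}
#'     \item{center_freqs}{centre frequency in Hz per scale, strictly
#'       decreasing.}
#'     \item{scales}{scale (in samples) per row.}
#'     \item{coi_freq}{per-time-index boundary frequency in Hz below which a
#'       coefficient is edge-affected (`Inf` at the edges).}
#'     \item{coi_halfwidth}{per-scale half-width, in samples, of the
#'       edge-affected zone.}
#'     \item{fs, n}{sampling rate and length.}
#'   }
#' @export
morse_cwt <- function(sig, params = morse_params()) {
  stopifnot(inherits(sig, "ispc_signal"))
  fb <- morse_filterbank(sig$n, sig$fs, params)
  cwt_from_filterbank(sig$samples, fb)
}

# Core transform given a prebuilt filter bank; used directly by the
# white-noise Monte Carlo so the bank is built once.
cwt_from_filterbank <- function(x, fb, scale_subset = NULL) {
  xp <- c(x, numeric(fb$padlen - length(x)))
  X <- stats::fft(xp)
  psi <- if (is.null(scale_subset)) fb$psi else fb$psi[, scale_subset, drop = FALSE]
  W <- stats::mvfft(psi * X, inverse = TRUE) / fb$padlen
  W <- t(W[seq_along(x), , drop = FALSE]) # u x n
  idx <- if (is.null(scale_subset)) seq_along(fb$freqs) else scale_subset
  structure(
    list(coeffs = W,
         center_freqs = fb$freqs[idx],
         scales = fb$scales[idx],
         coi_freq = coi_boundary_freq(fb),
         coi_halfwidth = coi_halfwidth(fb)[idx],
         fs = fb$fs, n = fb$n, params = fb$params, te1 = fb$te1, wp = fb$wp),
    class = "ispc_cwt"
  )
}

#' @export
print.ispc_cwt <- function(x, ...) {
  cat(sprintf(
    "<ispc_cwt> %d scales x %d samples @ %g Hz; centre freqs %.4g-%.4g Hz (%s voices/octave)\n",
    nrow(x$coeffs), x$n, x$fs, min(x$center_freqs), max(x$center_freqs),
    format(x$params$voices_per_octave)))
  invisible(x)
}

#' Cone-of-influence mask of a wavelet decomposition
#'
#' Entry `(a, k)` is `TRUE` when the coefficient at scale `a`, time index `k`
#' is free of edge effects, i.e. the scale's edge-effect half-width (the
#' wavelet envelope's one-sided e-folding time) fits between `k` and the
#' nearer signal edge. Equivalently, the scale's centre frequency lies above
#' the COI boundary frequency at time `k`. Rows are all-`FALSE` for scales so
#' wide that no sample escapes the edges.
#'
#' @param res an `ispc_cwt` from [morse_cwt()].
#' @return logical matrix of the same dimension as `res$coeffs`.
#' @export
in_coi_mask <- function(res) {
  stopifnot(inherits(res, "ispc_cwt"))
  n <- res$n
  d <- pmin(seq_len(n) - 1L, n - seq_len(n)) # distance to nearest edge, samples
  outer(res$coi_halfwidth, d, `<=`)
}
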