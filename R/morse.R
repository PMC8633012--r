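#' Generalized Morse wavelet parameters
#'
#' The analytic generalized Morse wavelet has frequency-domain form
#' `psi(w) = 2 (w / wp)^beta exp(-(w^gamma - wp^gamma))` for `w > 0` (zero for
#' `w <= 0`), with peak frequency `wp = (beta/gamma)^(1/gamma)`. `gamma`
#' controls the high-frequency decay and `beta` the low-frequency behaviour.
#' `gamma = 3` (the "Airy" family) with `beta = 20` matches the defaults of
#' the common MATLAB implementation, whose order symbol corresponds to `beta`
#' here (time-bandwidth product `P^2 = beta * gamma = 60`).
#'
#' @param gamma family parameter (> 0), default 3.
#' @param beta order / low-frequency-behaviour parameter (> 0), default 20.
#' @param voices_per_octave scales per octave of the logarithmic scale grid
#'   (>= 1), default 10.
#' @param freq_limits optional `c(min_hz, max_hz)` for the centre-frequency
#'   grid; default spans as wide as the signal length and sampling rate
#'   permit (see [morse_cwt()]).
#' @return an object of class `morse_params`.
#' @export
morse_params <- function(gamma = 3, beta = 20, voices_per_octave = 10,
                         freq_limits = NULL) {
  if (!is.numeric(gamma) || gamma <= 0 || !is.numeric(beta) || beta <= 0) {
    ispct_stop("invalid_params", "`gamma` and `beta` must be positive")
  }
  if (!is.numeric(voices_per_octave) || voices_per_octave < 1) {
    ispct_stop("invalid_params", "`voices_per_octave` must be >= 1")
  }
  if (!is.null(freq_limits)) {
    if (length(freq_limits) != 2L || any(freq_limits <= 0) ||
        freq_limits[1] >= freq_limits[2]) {
      ispct_stop("invalid_params", "`freq_limits` must be c(min, max) with 0 < min < max")
    }
  }
  structure(
    list(gamma = gamma, beta = beta,
         voices_per_octave = voices_per_octave, freq_limits = freq_limits),
    class = "morse_params"
  )
}

# Frequency-domain Morse wavelet evaluated at radian frequencies `w`
# (vectorized; zero at w <= 0). Computed in log space for stability.
morse_psihat <- function(w, gamma, beta) {
  wp <- (beta / gamma)^(1 / gamma)
  out <- numeric(length(w))
  pos <- w > 0
  lw <- log(w[pos])
  out[pos] <- 2 * exp(beta * (lw - log(wp)) - (exp(gamma * lw) - wp^gamma))
  out
}

# One-sided e-folding time of the mother wavelet's time-domain envelope, in
# natural (scale-1) time units. Obtained numerically from a finely sampled
# inverse FFT of the frequency response; cached per (gamma, beta).
.morse_cache <- new.env(parent = emptyenv())

morse_efold_time <- function(gamma, beta) {
  key <- sprintf("%.12g_%.12g", gamma, beta)
  if (!is.null(.morse_cache[[key]])) return(.morse_cache[[key]])
  wp <- (beta / gamma)^(1 / gamma)
  # upper frequency where the response has decayed to ~1e-16 of peak
  f <- function(w) beta * log(w / wp) - (w^gamma - wp^gamma) + 16 * log(10)
  hi <- wp
  while (f(hi) > 0) hi <- hi * 2
  nfft <- 2^15
  dw <- hi / (nfft / 2)
  w <- (seq_len(nfft) - 1) * dw
  psi <- stats::fft(morse_psihat(w, gamma, beta), inverse = TRUE) * dw / (2 * pi)
  env <- Mod(psi)
  dt <- 2 * pi / (nfft * dw)
  thr <- env[1] / exp(1)
  # envelope peaks at t = 0 (bin 1); walk outward on each side to the first
  # sub-threshold crossing and linearly interpolate
  first_cross <- function(e) {
    below <- which(e < thr)
    if (!length(below)) return(Inf)
    j <- below[1]
    if (j == 1L) return(0)
    (j - 2L + (thr - e[j - 1L]) / (e[j] - e[j - 1L])) * dt
  }
  te_pos <- first_cross(env[seq_len(nfft %/% 2)])
  te_neg <- first_cross(c(env[1], env[seq(nfft, nfft %/% 2 + 1L)]))
  te <- max(te_pos, te_neg)
  .morse_cache[[key]] <- te
  te
}

# Filter bank: everything scale-related for a given (n, fs, params).
# Scales are in samples; row a of `psi` is not stored -- `psi` is the
# (padlen x u) frequency-domain filter matrix with columns ordered from
# smallest scale (highest centre frequency) to largest.
morse_filterbank <- function(n, fs, params) {
  stopifnot(inherits(params, "morse_params"))
  gamma <- params$gamma; beta <- params$beta
  wp <- (beta / gamma)^(1 / gamma)
  te1 <- morse_efold_time(gamma, beta)
  f_of_scale <- function(s) wp * fs / (2 * pi * s)
  scale_of_f <- function(f) wp * fs / (2 * pi * f)

  f_hi_max <- fs / 2                      # peak at Nyquist
  s_lo_max <- ((n - 1) / 2) / te1         # widest scale whose COI reaches mid-signal
  f_lo_min <- f_of_scale(s_lo_max)
  if (is.null(params$freq_limits)) {
    f_max <- f_hi_max; f_min <- f_lo_min
  } else {
    f_min <- max(params$freq_limits[1], f_of_scale(((n - 1)) / te1 * 4)) # hard floor
    f_max <- min(params$freq_limits[2], fs / 2)
  }
  if (!(f_max > f_min) || log2(f_max / f_min) < 2) {
    ispct_stop("signal_too_short", sprintf(
      "signal too short for at least 2 octaves of scales (usable band %.4g-%.4g Hz)",
      f_min, f_max))
  }
  v <- params$voices_per_octave
  n_oct <- log2(f_max / f_min)
  j <- 0:floor(n_oct * v)
  freqs <- f_max / 2^(j / v)              # strictly decreasing
  scales <- scale_of_f(freqs)
  # zero-pad to an FFT-friendly 5-smooth composite length with at least 15%
  # headroom: keeps R's FFT in the fast mixed-radix regime with less padding
  # than the next power of two, while the pad stays several e-folding times
  # longer than any retained scale's envelope, so circular wrap-around onto
  # in-COI coefficients is negligible
  padlen <- next_5smooth(ceiling(1.15 * n))
  wk <- 2 * pi * (0:(padlen - 1)) / padlen
  wk[wk > pi] <- 0                         # negative-frequency bins: analytic wavelet is zero there
  psi <- vapply(scales, function(s) morse_psihat(s * wk, gamma, beta),
                numeric(padlen))
  psi[1, ] <- 0
  list(n = n, fs = fs, params = params, padlen = padlen,
       scales = scales, freqs = freqs, te1 = te1, wp = wp, psi = psi)
}

# Half-width, in samples, of the edge-affected zone at each scale.
coi_halfwidth <- function(fb) fb$scales * fb$te1

# Per-time-index COI boundary frequency in Hz: at time index k (1-based), the
# lowest centre frequency still free of edge effects. Inf at the very edges.
coi_boundary_freq <- function(fb) {
  n <- fb$n
  d <- pmin(seq_len(n) - 1L, n - seq_len(n))
  out <- rep(Inf, n)
  pos <- d > 0
  out[pos] <- fb$wp * fb$fs / (2 * pi * (d[pos] / fb$te1))
  out
}
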