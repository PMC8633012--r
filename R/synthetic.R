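# Validation-signal generators. All use the t = (1:n)/fs time convention
# (first sample at t = dt) and are deterministic given their seed. Default
# length and rate (50 s at 1 kHz) match the synthetic validation settings.

hanning <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

synth_time <- function(fs, duration) {
  n <- as.integer(round(fs * duration))
  list(n = n, t = seq_len(n) / fs)
}

synth_noise <- function(n, noise_sd, seed, stage) {
  if (noise_sd < 0) ispct_stop("invalid_params", "`noise_sd` must be >= 0")
  if (noise_sd == 0) return(numeric(n))
  with_seed(derive_seed(seed, stage), stats::rnorm(n, sd = noise_sd))
}

#' Double sinusoid validation signal
#'
#' Two sinusoids plus low-amplitude Gaussian noise, the whole sum enveloped
#' by a Hanning window (zero at both ends, which also guarantees a clean
#' clip point).
#'
#' Because the envelope spans the entire record, \emph{every} scale's power
#' series carries the same slow modulation. The significance test therefore
#' flags broad co-modulation across nearly all scale pairs — a genuine
#' property of this signal — while the tone-core pairs themselves are
#' untestable: a whole-record envelope leaves a power series with only a few
#' effective degrees of freedom, so its null correlation spread is enormous.
#' See the package vignette for the full discussion.
#'
#' @param fs sampling rate (Hz), default 1000.
#' @param duration length in seconds, default 50.
#' @param f1,f2 sinusoid frequencies (Hz), defaults 10 and 50.
#' @param noise_sd Gaussian noise standard deviation relative to the unit
#'   carrier amplitude, default 0.05.
#' @param seed RNG seed for the noise component.
#' @return an [ispc_signal].
#' @export
gen_double_sinusoid <- function(fs = 1000, duration = 50, f1 = 10, f2 = 50,
                                noise_sd = 0.05, seed = 1) {
  g <- synth_time(fs, duration)
  x <- (sin(2 * pi * f1 * g$t) + sin(2 * pi * f2 * g$t) +
          synth_noise(g$n, noise_sd, seed, "double_sinusoid")) * hanning(g$n)
  ispc_signal(x, fs, meta = "double_sinusoid")
}

#' Double pulse validation signal
#'
#' Two Hanning-modulated sinusoidal pulses at distinct times and carrier
#' frequencies, with Gaussian noise throughout. Expected significance map:
#' one main on-diagonal grouping per carrier.
#'
#' @inheritParams gen_double_sinusoid
#' @param f1,f2 carrier frequencies (Hz), defaults 30 and 5.
#' @param interval1,interval2 pulse intervals in seconds, defaults
#'   `c(10, 10.5)` and `c(25, 26.5)`.
#' @return an [ispc_signal].
#' @export
gen_double_pulse <- function(fs = 1000, duration = 50,
                             f1 = 30, interval1 = c(10, 10.5),
                             f2 = 5, interval2 = c(25, 26.5),
                             noise_sd = 0.05, seed = 1) {
  g <- synth_time(fs, duration)
  x <- synth_noise(g$n, noise_sd, seed, "double_pulse")
  for (p in list(list(f = f1, iv = interval1), list(f = f2, iv = interval2))) {
    k <- which(g$t >= p$iv[1] & g$t <= p$iv[2])
    x[k] <- x[k] + sin(2 * pi * p$f * (g$t[k] - p$iv[1])) * hanning(length(k))
  }
  ispc_signal(x, fs, meta = "double_pulse")
}

#' Double chirp validation signal
#'
#' Two Hanning-enveloped chirps whose instantaneous frequency increases
#' quadratically across their interval, with Gaussian noise throughout. The
#' phase is the closed-form integral of the quadratic instantaneous
#' frequency, `phi(tau) = 2 pi (f0 tau + (f1 - f0) tau^3 / (3 T^2))`.
#'
#' @inheritParams gen_double_sinusoid
#' @param sweep1,sweep2 frequency sweeps `c(from_hz, to_hz)`, defaults
#'   `c(20, 50)` and `c(1, 5)`.
#' @param interval1,interval2 chirp intervals in seconds, defaults
#'   `c(10, 10.5)` and `c(25, 26.5)`.
#' @return an [ispc_signal].
#' @export
gen_double_chirp <- function(fs = 1000, duration = 50,
                             sweep1 = c(20, 50), interval1 = c(10, 10.5),
                             sweep2 = c(1, 5), interval2 = c(25, 26.5),
                             noise_sd = 0.05, seed = 1) {
  g <- synth_time(fs, duration)
  x <- synth_noise(g$n, noise_sd, seed, "double_chirp")
  for (p in list(list(sw = sweep1, iv = interval1),
                 list(sw = sweep2, iv = interval2))) {
    k <- which(g$t >= p$iv[1] & g$t <= p$iv[2])
    tau <- g$t[k] - p$iv[1]
    Tn <- p$iv[2] - p$iv[1]
    phase <- 2 * pi * (p$sw[1] * tau + (p$sw[2] - p$sw[1]) * tau^3 / (3 * Tn^2))
    x[k] <- x[k] + sin(phase) * hanning(length(k))
  }
  ispc_signal(x, fs, meta = "double_chirp")
}

#' Square-wave validation signal
#'
#' Truncated odd-harmonic Fourier expansion of a square wave,
#' `(4/pi) * sum_j sin((2j-1) w t) / (2j-1)` plus Gaussian noise. Power in
#' every harmonic band co-varies, so most well-separated pairs should be
#' significant — except near-diagonal low-frequency pairs, where the test is
#' deliberately conservative.
#'
#' @inheritParams gen_double_sinusoid
#' @param f fundamental frequency (Hz), default 2.
#' @param n_harmonics number of odd harmonics; default all with frequency
#'   below Nyquist. Raises condition `ispct_alias` if the requested harmonics
#'   reach or exceed Nyquist.
#' @return an [ispc_signal].
#' @export
gen_square_wave <- function(fs = 1000, duration = 50, f = 2,
                            n_harmonics = NULL, noise_sd = 0.05, seed = 1) {
  g <- synth_time(fs, duration)
  max_h <- floor((fs / 2 - 1e-9) / f + 1) / 2 # largest j with (2j-1) f < fs/2
  max_h <- floor(max_h)
  if (is.null(n_harmonics)) n_harmonics <- max_h
  if (n_harmonics < 1) ispct_stop("invalid_params", "need at least 1 harmonic")
  if ((2 * n_harmonics - 1) * f >= fs / 2) {
    ispct_stop("alias", sprintf(
      "harmonic %d at %.4g Hz reaches the Nyquist frequency %.4g Hz",
      n_harmonics, (2 * n_harmonics - 1) * f, fs / 2))
  }
  w <- 2 * pi * f
  x <- numeric(g$n)
  for (j in seq_len(n_harmonics)) {
    h <- 2 * j - 1
    x <- x + sin(h * w * g$t) / h
  }
  x <- 4 / pi * x + synth_noise(g$n, noise_sd, seed, "square_wave")
  ispc_signal(x, fs, meta = "square_wave")
}

#' Exponential validation signal
#'
#' `x(t) = exp(t)` plus Gaussian noise: strongly monotonous, so no late
#' sample recurs near the first one and [clip_to_cycle()] must reject it —
#' the canonical out-of-domain input. Durations beyond ~709 s would overflow
#' double precision; the exponent is capped there (far outside the intended
#' 50 s use).
#'
#' @inheritParams gen_double_sinusoid
#' @return an [ispc_signal].
#' @export
gen_exponential <- function(fs = 1000, duration = 50, noise_sd = 0.05, seed = 1) {
  g <- synth_time(fs, duration)
  x <- exp(pmin(g$t, 709)) + synth_noise(g$n, noise_sd, seed, "exponential")
  ispc_signal(x, fs, meta = "exponential")
}

#' White-noise validation signal
#'
#' Uniform white noise on `[0, 1]` by default (`kind = "uniform"`), or
#' standard Gaussian. Zero-meaning happens downstream in preprocessing. The
#' correct test outcome is an empty significance mask.
#'
#' @inheritParams gen_double_sinusoid
#' @param kind `"uniform"` (default) or `"gaussian"`.
#' @return an [ispc_signal].
#' @export
gen_white_noise <- function(fs = 1000, duration = 50,
                            kind = c("uniform", "gaussian"), seed = 1) {
  kind <- match.arg(kind)
  g <- synth_time(fs, duration)
  x <- with_seed(derive_seed(seed, "white_noise_signal"), {
    if (kind == "uniform") stats::runif(g$n) else stats::rnorm(g$n)
  })
  ispc_signal(x, fs, meta = paste0("white_noise_", kind))
}

#' Generate any validation signal by name
#'
#' Dispatcher over the individual `gen_*` generators.
#'
#' @param kind one of `"double_sinusoid"`, `"double_pulse"`,
#'   `"double_chirp"`, `"square_wave"`, `"exponential"`, `"white_noise"`.
#' @param ... forwarded to the generator.
#' @return an [ispc_signal].
#' @export
synth_signal <- function(kind = c("double_sinusoid", "double_pulse",
                                  "double_chirp", "square_wave",
                                  "exponential", "white_noise"), ...) {
  kind <- match.arg(kind)
  switch(kind,
         double_sinusoid = gen_double_sinusoid(...),
         double_pulse = gen_double_pulse(...),
         double_chirp = gen_double_chirp(...),
         square_wave = gen_square_wave(...),
         exponential = gen_exponential(...),
         white_noise = gen_white_noise(...))
}
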