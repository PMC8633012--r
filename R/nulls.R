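# Power of the retained scales of a signal, through a prebuilt filter bank,
# restricted to the analysis window. The analytic wavelet's frequency
# response is zero above Nyquist, so only the first half of the spectrum is
# multiplied; the inverse FFT runs over all scales at once.
bank_power <- function(x, psi_h, padlen, rows) {
  X <- stats::fft(c(x, numeric(padlen - length(x))))
  Z <- matrix(0i, padlen, ncol(psi_h))
  nh <- nrow(psi_h)
  Z[seq_len(nh), ] <- psi_h * X[seq_len(nh)]
  W <- stats::mvfft(Z, inverse = TRUE)[rows, , drop = FALSE] / padlen
  Mod(W)^2
}

psi_half <- function(fb, keep) {
  fb$psi[seq_len(fb$padlen %/% 2 + 1L), keep, drop = FALSE]
}

# Shared COI retention rule: which scales keep >= min_frac of their samples
# inside the COI, and the common fully-in-COI window. Used both by coi_trim()
# and by the white-noise Monte Carlo, so data and null are guaranteed to live
# on the same grid for a given signal length.
coi_geometry <- function(n, halfwidths, min_frac) {
  d <- pmin(seq_len(n) - 1L, n - seq_len(n))
  frac_in <- vapply(halfwidths, function(h) mean(d >= h), numeric(1))
  keep <- which(frac_in >= min_frac)
  if (!length(keep)) {
    ispct_stop("nothing_retained",
               "no scale has the required fraction of samples inside the COI")
  }
  inside <- which(d >= max(halfwidths[keep]))
  list(keep = keep, k1 = inside[1], k2 = inside[length(inside)])
}

#' Mean white-noise inter-scale correlation matrix (frequency-oversampling null)
#'
#' Adjacent scales of a continuous wavelet transform overlap in frequency, so
#' their power series are correlated regardless of the input — an intrinsic
#' bias of the decomposition. This function estimates that bias by Monte
#' Carlo: `L` independent white-noise signals of the same length as the
#' analysed (clipped) data are pushed through the identical decomposition
#' path (CWT, power, COI filtering, common window, Pearson matrix) and the
#' element-wise mean correlation matrix is returned. For white noise the
#' power in each band is serially unstructured, so the mean inter-scale
#' correlation isolates the frequency-domain oversampling: chance
#' correlations between independently autocorrelated rows average to zero.
#'
#' The retained scale grid is a deterministic function of the signal length
#' and the COI rule, so it matches the analysed data's grid by construction.
#'
#' @param n signal length in samples (after clipping / length
#'   standardization, i.e. the length actually decomposed).
#' @param fs sampling rate in Hz.
#' @param params a [morse_params()].
#' @param L number of Monte Carlo iterations (>= 2). 1000 is appropriate for
#'   real analyses; the synthetic validation suite uses 250.
#' @param noise_kind `"gaussian"` (default) or `"uniform"` white noise; the
#'   correlation matrix is scale-free so the choice is second-order.
#' @param seed root seed; per-iteration seeds are derived with
#'   [derive_seed()].
#' @param min_in_coi_frac COI retention threshold, as in [coi_trim()].
#' @param window optional `c(k1, k2)` overriding the correlation window
#'   (must lie inside the common fully-in-COI window).
#' @return object of class `wn_null`: list with `rho_bar` (symmetric mean
#'   correlation matrix, unit diagonal), `freqs`, `L`, `noise_kind`, `seed`,
#'   `n`, `fs`, `window`, `signal_length_s`.
#' @export
white_noise_mean_ispcm <- function(n, fs, params = morse_params(), L = 1000,
                                   noise_kind = c("gaussian", "uniform"),
                                   seed = 1, min_in_coi_frac = 0.9,
                                   window = NULL) {
  noise_kind <- match.arg(noise_kind)
  if (L < 2) ispct_stop("invalid_params", "`L` must be >= 2")
  fb <- morse_filterbank(n, fs, params)
  geo <- coi_geometry(n, coi_halfwidth(fb), min_in_coi_frac)
  if (is.null(window)) {
    window <- c(geo$k1, geo$k2)
  } else if (window[1] < geo$k1 || window[2] > geo$k2) {
    ispct_stop("invalid_params", "`window` must lie inside the fully-in-COI window")
  }
  keep <- geo$keep
  psi_h <- psi_half(fb, keep)
  rows <- window[1]:window[2]
  u <- length(keep)
  acc <- matrix(0, u, u)
  for (v in seq_len(L)) {
    noise <- with_seed(derive_seed(seed, "white_noise", v), {
      if (noise_kind == "gaussian") stats::rnorm(n) else stats::runif(n)
    })
    acc <- acc + fast_cor(bank_power(noise - mean(noise), psi_h, fb$padlen, rows))
  }
  rho_bar <- acc / L
  rho_bar <- (rho_bar + t(rho_bar)) / 2
  diag(rho_bar) <- 1
  freqs <- fb$freqs[keep]
  dimnames(rho_bar) <- list(signif(freqs, 6), signif(freqs, 6))
  structure(
    list(rho_bar = rho_bar, freqs = freqs, L = L, noise_kind = noise_kind,
         seed = seed, n = n, fs = fs, window = window,
         signal_length_s = n / fs, params = params,
         min_in_coi_frac = min_in_coi_frac),
    class = "wn_null"
  )
}

#' @export
print.wn_null <- function(x, ...) {
  cat(sprintf(
    "<wn_null> mean %s white-noise ISPCM, %d scales, L = %d, n = %d @ %g Hz\n",
    x$noise_kind, nrow(x$rho_bar), x$L, x$n, x$fs))
  invisible(x)
}

#' Phase-randomization null for intra-scale autocorrelation
#'
#' The power series of a wide scale is strongly autocorrelated — partly from
#' the transform's time-domain oversampling, partly from any non-stationarity
#' of the signal itself — and cross-correlations between autocorrelated
#' series have inflated variance under the null of no association. This
#' function estimates the null spread per scale pair by Monte Carlo: in each
#' of `H` iterations a phase-randomized surrogate of the data is built, its
#' inter-scale Pearson matrix computed, and the per-pair mean and unbiased
#' sample variance across iterations returned as a normal null.
#'
#' Two surrogate scopes are supported:
#' \describe{
#'   \item{`scope = "scale"` (default)}{Each retained scale's \emph{power
#'     series} is independently phase-randomized, preserving its full
#'     autocovariance (including any non-stationary slow modulation) while
#'     destroying all cross-scale alignment. The null mean is ~0 for every
#'     pair. Appropriate for broadband stochastic data; very conservative
#'     for signals dominated by a shared deterministic envelope, whose power
#'     series have few effective degrees of freedom.}
#'   \item{`scope = "signal"`}{The original (clipped) \emph{signal} is
#'     phase-randomized as a whole and re-decomposed through the identical
#'     CWT/COI path, i.e. the null hypothesis is a stationary signal with
#'     the data's amplitude spectrum. Destroys deterministic envelopes, so
#'     shared slow power modulation becomes detectable; the surrogate pairs
#'     retain the transform's frequency-overlap correlation, so the null
#'     mean is \emph{not} zero near the diagonal. Used by the synthetic
#'     validation suite. Requires `sig`.}
#' }
#'
#' With the FT method and `scope = "scale"`, the column FFTs are computed
#' once and re-randomized each iteration. The IAAFT method preserves the
#' sample histogram as well but its nulls are often non-normal, which
#' conflicts with the downstream multiple-testing procedure; it is retained
#' as an option.
#'
#' @param tw an `ispc_wps_trimmed` from [coi_trim()].
#' @param H Monte Carlo iterations (>= 30 recommended so mean and variance
#'   are estimated reliably; around 250 for real analyses, 150 in the
#'   synthetic validation suite).
#' @param method `"ft"` (default) or `"iaaft"`.
#' @param seed root seed.
#' @param scope `"scale"` (randomize each power series) or `"signal"`
#'   (randomize the signal and re-decompose).
#' @param sig the clipped [ispc_signal] that produced `tw`; required for
#'   `scope = "signal"`.
#' @param iaaft_max_iter iteration cap per IAAFT surrogate.
#' @return object of class `pr_null`: list with `phi_bar` and `phi_var`
#'   (symmetric matrices; diagonal 1 and 0 by convention, excluded from
#'   testing), `samples` (`H x` n_pairs matrix of null correlations, pairs in
#'   column-major upper-triangle order), `H`, `method`, `scope`, `seed`,
#'   `freqs`.
#' @export
phase_rand_null <- function(tw, H = 250, method = c("ft", "iaaft"), seed = 1,
                            scope = c("scale", "signal"), sig = NULL,
                            iaaft_max_iter = 100) {
  stopifnot(inherits(tw, "ispc_wps_trimmed"))
  method <- match.arg(method)
  scope <- match.arg(scope)
  if (H < 2) ispct_stop("invalid_params", "`H` must be >= 2")
  x <- t(tw$power) # m samples x u scales
  m <- nrow(x); u <- ncol(x)
  up <- upper.tri(matrix(0, u, u))
  samples <- matrix(NA_real_, H, sum(up))
  nonconv <- 0L
  if (scope == "signal") {
    if (!inherits(sig, "ispc_signal") || sig$n != tw$n_original) {
      ispct_stop("invalid_params",
                 "`scope = \"signal\"` needs the clipped signal that produced `tw`")
    }
    fb <- morse_filterbank(tw$n_original, tw$fs, tw$params)
    psi_h <- psi_half(fb, tw$retained_scales)
    rows <- tw$time_window[1]:tw$time_window[2]
    for (h in seq_len(H)) {
      sd_h <- derive_seed(seed, "phase_rand", h)
      xs <- if (method == "ft") {
        ft_phase_randomize(sig$samples, seed = sd_h)
      } else {
        s <- iaaft_phase_randomize(sig$samples, max_iter = iaaft_max_iter,
                                   seed = sd_h)
        if (!attr(s, "converged")) nonconv <- nonconv + 1L
        as.numeric(s)
      }
      samples[h, ] <- fast_cor(bank_power(xs, psi_h, fb$padlen, rows))[up]
    }
  } else if (method == "ft") {
    F <- stats::mvfft(x)
    for (h in seq_len(H)) {
      M <- with_seed(derive_seed(seed, "phase_rand", h),
                     ft_randomize_columns(F, m))
      samples[h, ] <- fast_cor(M)[up]
    }
  } else {
    for (h in seq_len(H)) {
      M <- matrix(0, m, u)
      for (a in seq_len(u)) {
        s <- iaaft_phase_randomize(x[, a], max_iter = iaaft_max_iter,
                                   seed = derive_seed(seed, sprintf("iaaft_%d", h), a))
        if (!attr(s, "converged")) nonconv <- nonconv + 1L
        M[, a] <- as.numeric(s)
      }
      samples[h, ] <- fast_cor(M)[up]
    }
  }
  if (nonconv > 0) {
    ispct_warn("iaaft_nonconverged", sprintf(
      "%d IAAFT surrogate(s) hit the iteration cap; best iterate used", nonconv))
  }
  mu <- colMeans(samples)
  va <- apply(samples, 2L, stats::var) # unbiased, divisor H - 1
  phi_bar <- matrix(0, u, u); phi_var <- matrix(0, u, u)
  phi_bar[up] <- mu; phi_var[up] <- va
  phi_bar <- phi_bar + t(phi_bar); phi_var <- phi_var + t(phi_var)
  diag(phi_bar) <- 1
  freqs <- tw$retained_freqs
  dimnames(phi_bar) <- dimnames(phi_var) <- list(signif(freqs, 6), signif(freqs, 6))
  structure(
    list(phi_bar = phi_bar, phi_var = phi_var, samples = samples,
         H = H, method = method, scope = scope, seed = seed, freqs = freqs,
         n_window = m),
    class = "pr_null"
  )
}

#' @export
print.pr_null <- function(x, ...) {
  cat(sprintf(
    "<pr_null> %s/%s phase-randomization null, %d scales, H = %d; median pair SD %.4g\n",
    toupper(x$method), x$scope %||% "scale", nrow(x$phi_bar), x$H,
    stats::median(sqrt(x$phi_var[upper.tri(x$phi_var)]))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combine the two null elements into the per-pair normal null
#'
#' The null for pair `(a, b)` is `N(rho_bar + phi_bar, Var(phi))`: the mean
#' white-noise correlation (frequency-oversampling bias) shifts the centre,
#' and the phase-randomization spread supplies the variance. Adding the bias
#' to the null mean is equivalent to subtracting it from the measured
#' correlation — a deliberately conservative correction near the diagonal,
#' where scale overlap is strongest.
#'
#' @param wn a `wn_null` from [white_noise_mean_ispcm()].
#' @param pr a `pr_null` from [phase_rand_null()] on the same scale grid.
#' @return object of class `ispc_null`: list with `mean`, `var` (symmetric
#'   matrices, `NA` diagonal — self-correlations are not tested) and
#'   `provenance` (L, H, seeds, noise kind, method, grid).
#' @export
combine_null <- function(wn, pr) {
  stopifnot(inherits(wn, "wn_null"), inherits(pr, "pr_null"))
  if (length(wn$freqs) != length(pr$freqs) ||
      any(abs(wn$freqs - pr$freqs) > 1e-9 * pr$freqs)) {
    ispct_stop("grid_mismatch",
               "white-noise and phase-randomization nulls are on different scale grids")
  }
  mu <- wn$rho_bar + pr$phi_bar
  va <- pr$phi_var
  diag(mu) <- NA_real_
  diag(va) <- NA_real_
  structure(
    list(mean = mu, var = va, freqs = pr$freqs,
         provenance = list(L = wn$L, H = pr$H,
                           wn_seed = wn$seed, pr_seed = pr$seed,
                           noise_kind = wn$noise_kind, method = pr$method,
                           scope = pr$scope %||% "scale",
                           n = wn$n, fs = wn$fs, window = wn$window)),
    class = "ispc_null"
  )
}

#' @export
print.ispc_null <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "<ispc_null> %d scales; N(rho_bar + phi_bar, Var(phi)); L = %d, H = %d (%s/%s)\n",
    nrow(x$mean), p$L, p$H, p$noise_kind, toupper(p$method)))
  invisible(x)
}

#' Normality diagnostics of the phase-randomization null
#'
#' The multiple-testing step assumes the per-pair null distributions are
#' normal. This checks each pair's `H` Monte Carlo correlations with a
#' Shapiro-Wilk test and controls the FDR over pairs with Benjamini-Hochberg;
#' the fraction of pairs whose normality is \emph{not} rejected is reported.
#'
#' @param pr a `pr_null` (its `samples` matrix is used).
#' @param alpha FDR level for the normality rejection, default 0.05.
#' @return list of class `ispc_normality`: `p` (raw p-values per pair),
#'   `p_adj`, `pass_fraction`, `alpha`, `H`.
#' @export
normality_diagnostics <- function(pr, alpha = 0.05) {
  stopifnot(inherits(pr, "pr_null"))
  if (alpha <= 0 || alpha >= 1) ispct_stop("invalid_alpha", "`alpha` must be in (0, 1)")
  p <- apply(pr$samples, 2L, function(s) stats::shapiro.test(s)$p.value)
  p_adj <- stats::p.adjust(p, method = "BH")
  structure(
    list(p = p, p_adj = p_adj, pass_fraction = mean(p_adj > alpha),
         alpha = alpha, H = pr$H),
    class = "ispc_normality"
  )
}

#' @export
print.ispc_normality <- function(x, ...) {
  cat(sprintf(
    "<ispc_normality> %.1f%% of %d pairs consistent with normality (FDR alpha = %g, H = %d)\n",
    100 * x$pass_fraction, length(x$p), x$alpha, x$H))
  invisible(x)
}
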