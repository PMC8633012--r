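#' Wavelet power spectrum
#'
#' Element-wise squared modulus of the wavelet coefficients, with the COI
#' mask carried along.
#'
#' @param res an `ispc_cwt` from [morse_cwt()].
#' @return an object of class `ispc_wps` with fields `power` (nonnegative
#'   `u x n` matrix), `center_freqs`, `coi_mask`, `fs`, `n`, plus the COI
#'   geometry needed for trimming.
#' @export
compute_wps <- function(res) {
  stopifnot(inherits(res, "ispc_cwt"))
  structure(
    list(power = Mod(res$coeffs)^2,
         center_freqs = res$center_freqs,
         scales = res$scales,
         coi_mask = in_coi_mask(res),
         coi_halfwidth = res$coi_halfwidth,
         fs = res$fs, n = res$n, params = res$params),
    class = "ispc_wps"
  )
}

#' @export
print.ispc_wps <- function(x, ...) {
  cat(sprintf("<ispc_wps> %d scales x %d samples; %.1f%% of cells inside the COI\n",
              nrow(x$power), ncol(x$power), 100 * mean(x$coi_mask)))
  invisible(x)
}

#' Filter a power spectrum against the cone of influence
#'
#' Two steps: (1) scales with fewer than `min_in_coi_frac` of their samples
#' inside the COI are removed; (2) a common leading/trailing time window is
#' trimmed so that every retained (scale, time) cell is inside the COI. The
#' retained window is the widest common window, which (because COI spans are
#' nested across scales) is exactly the in-COI span of the widest retained
#' scale. A single common window makes every pairwise correlation use the
#' same samples, orders of magnitude cheaper than per-pair windows.
#'
#' @param wps an `ispc_wps` from [compute_wps()].
#' @param min_in_coi_frac minimum in-COI sample fraction for a scale to be
#'   retained; default 0.9.
#' @return an object of class `ispc_wps_trimmed` with fields `power`
#'   (retained scales x window), `retained_freqs`, `retained_scales` (indices
#'   into the original scale grid), `time_window` (`c(k_start, k_end)` sample
#'   indices into the original series), `fs`, `n_original`.
#' @export
coi_trim <- function(wps, min_in_coi_frac = 0.9) {
  stopifnot(inherits(wps, "ispc_wps"))
  if (min_in_coi_frac <= 0 || min_in_coi_frac > 1) {
    ispct_stop("invalid_params", "`min_in_coi_frac` must be in (0, 1]")
  }
  frac_in <- rowMeans(wps$coi_mask)
  keep <- which(frac_in >= min_in_coi_frac)
  if (!length(keep)) {
    ispct_stop("nothing_retained",
               "no scale has the required fraction of samples inside the COI")
  }
  # widest retained scale determines the common fully-in-COI window
  hw <- max(wps$coi_halfwidth[keep])
  n <- wps$n
  d <- pmin(seq_len(n) - 1L, n - seq_len(n))
  inside <- which(d >= hw)
  k1 <- inside[1]; k2 <- inside[length(inside)]
  structure(
    list(power = wps$power[keep, k1:k2, drop = FALSE],
         retained_freqs = wps$center_freqs[keep],
         retained_scales = keep,
         time_window = c(k1, k2),
         fs = wps$fs, n_original = n, params = wps$params,
         min_in_coi_frac = min_in_coi_frac),
    class = "ispc_wps_trimmed"
  )
}

#' @export
print.ispc_wps_trimmed <- function(x, ...) {
  cat(sprintf(
    "<ispc_wps_trimmed> %d scales (%.4g-%.4g Hz) x %d samples (window %d..%d of %d)\n",
    nrow(x$power), min(x$retained_freqs), max(x$retained_freqs),
    ncol(x$power), x$time_window[1], x$time_window[2], x$n_original))
  invisible(x)
}

#' Inter-scale power correlation matrix
#'
#' Time-wise Pearson correlation between every pair of retained scale power
#' series, over the common fully-in-COI window. Computed with standardized
#' matrix products; equal to the naive two-loop evaluation of the Pearson
#' formula to floating precision. Zero-variance (degenerate) scales cannot be
#' correlated: they are dropped with a warning (condition
#' `ispct_degenerate_scale`) and recorded in the result.
#'
#' @param tw an `ispc_wps_trimmed` from [coi_trim()].
#' @return an object of class `ispcm`: list with `r` (symmetric correlation
#'   matrix, unit diagonal), `freqs` (Hz labels), `n_used` (samples per
#'   correlation), `dropped_scales` (indices of degenerate scales, if any).
#' @export
pearson_ispcm <- function(tw) {
  stopifnot(inherits(tw, "ispc_wps_trimmed"))
  m <- ncol(tw$power)
  if (m < 3) ispct_stop("invalid_params", "retained window must span at least 3 samples")
  x <- t(tw$power)
  sds <- apply(x, 2L, stats::sd)
  drop <- which(sds == 0)
  freqs <- tw$retained_freqs
  if (length(drop)) {
    ispct_warn("degenerate_scale", sprintf(
      "%d zero-variance scale(s) excluded from the correlation matrix", length(drop)))
    x <- x[, -drop, drop = FALSE]
    freqs <- freqs[-drop]
  }
  if (ncol(x) < 2) ispct_stop("nothing_retained", "fewer than 2 non-degenerate scales")
  r <- fast_cor(x)
  dimnames(r) <- list(signif(freqs, 6), signif(freqs, 6))
  structure(
    list(r = r, freqs = freqs, n_used = m,
         dropped_scales = if (length(drop)) tw$retained_scales[drop] else integer(0)),
    class = "ispcm"
  )
}

#' @export
print.ispcm <- function(x, ...) {
  cat(sprintf(
    "<ispcm> %d x %d inter-scale Pearson correlations (%.4g-%.4g Hz), n = %d samples\n",
    nrow(x$r), ncol(x$r), min(x$freqs), max(x$freqs), x$n_used))
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("  off-diagonal range [%.3f, %.3f], median %.3f\n",
              min(off), max(off), stats::median(off)))
  invisible(x)
}

#' Write an inter-scale correlation matrix as delimited text
#'
#' Tab-separated with a centre-frequency header row and column.
#'
#' @param x an `ispcm` (or any matrix with frequency dimnames).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ispcm <- function(x, path) {
  m <- if (inherits(x, "ispcm")) x$r else x
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Export a wavelet power spectrum as delimited text
#'
#' Writes the power matrix (scales as rows, labelled by centre frequency)
#' and, alongside it, the COI boundary curve, for external plotting.
#'
#' @param wps an `ispc_wps` (for the COI curve, compute it from the
#'   originating `ispc_cwt` via [morse_cwt()]).
#' @param path output path for the power matrix; the COI curve goes to
#'   `<path>.coi` (two columns: time index, boundary frequency in Hz).
#' @param coi_freq optional numeric vector of per-sample COI boundary
#'   frequencies (e.g. `cwt$coi_freq`); written when supplied.
#' @return `path`, invisibly.
#' @export
write_wps <- function(wps, path, coi_freq = NULL) {
  stopifnot(inherits(wps, "ispc_wps"))
  m <- wps$power
  rownames(m) <- signif(wps$center_freqs, 6)
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = FALSE)
  if (!is.null(coi_freq)) {
    utils::write.table(
      data.frame(index = seq_along(coi_freq), coi_hz = coi_freq),
      paste0(path, ".coi"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
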