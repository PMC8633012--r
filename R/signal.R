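#' Construct a uniformly sampled signal
#'
#' The basic analysis object: a real-valued, uniformly sampled, single-channel
#' time series together with its sampling rate. All downstream functions
#' (clipping, wavelet decomposition, the significance test) operate on this
#' class.
#'
#' @param samples numeric vector of samples (arbitrary units); all finite,
#'   length >= 2.
#' @param fs sampling rate in Hz (> 0).
#' @param meta optional free-form label carried through the pipeline.
#' @return an object of class `ispc_signal` with fields `samples`, `fs`, `n`,
#'   `meta`.
#' @examples
#' sig <- ispc_signal(sin(2 * pi * 5 * (1:1000) / 250), fs = 250)
#' sig
#' @export
ispc_signal <- function(samples, fs, meta = NULL) {
  if (!is.numeric(samples) || length(samples) < 2L) {
    ispct_stop("invalid_signal", "`samples` must be a numeric vector of length >= 2")
  }
  if (!all(is.finite(samples))) {
    ispct_stop("invalid_signal", "all samples must be finite")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    ispct_stop("invalid_signal", "`fs` must be a single positive number")
  }
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         n = length(samples), meta = meta),
    class = "ispc_signal"
  )
}

#' @export
print.ispc_signal <- function(x, ...) {
  cat(sprintf("<ispc_signal> n = %d samples @ %g Hz (%.4g s)%s\n",
              x$n, x$fs, x$n / x$fs,
              if (is.null(x$meta)) "" else paste0("  [", x$meta, "]")))
  invisible(x)
}

#' Read a signal from disk
#'
#' Accepts either single-column delimited text (one sample per line, `#`
#' comments allowed) or a flat little-endian 64-bit float binary array.
#'
#' @param path file path.
#' @param fs sampling rate in Hz.
#' @param format `"text"` or `"f64"`; default guesses from the extension
#'   (`.bin`/`.f64`/`.dat` are read as binary, anything else as text).
#' @param meta optional label; defaults to the file name.
#' @return an [ispc_signal].
#' @export
read_signal <- function(path, fs, format = c("auto", "text", "f64"), meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) ispct_stop("io", sprintf("input file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(bin|f64|dat)$", path, ignore.case = TRUE)) "f64" else "text"
  }
  x <- if (format == "f64") {
    sz <- file.info(path)$size
    con <- file(path, "rb"); on.exit(close(con))
    readBin(con, what = "double", n = sz %/% 8L, size = 8L, endian = "little")
  } else {
    scan(path, what = double(), comment.char = "#", quiet = TRUE)
  }
  ispc_signal(x, fs, meta = if (is.null(meta)) basename(path) else meta)
}

#' Write a signal to disk
#'
#' @param sig an [ispc_signal].
#' @param path output path.
#' @param format `"text"` (one sample per line) or `"f64"` (flat little-endian
#'   doubles).
#' @return `path`, invisibly.
#' @export
write_signal <- function(sig, path, format = c("text", "f64")) {
  format <- match.arg(format)
  stopifnot(inherits(sig, "ispc_signal"))
  if (format == "f64") {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(sig$samples, con, size = 8L, endian = "little")
  } else {
    writeLines(formatC(sig$samples, format = "g", digits = 17), path)
  }
  invisible(path)
}

#' Clip a signal at its last near-recurrence of the first sample
#'
#' Truncates the series at the largest index `k2` such that `x[k2]` is within
#' a small tolerance of `x[1]`, then removes the mean. Matching first and last
#' samples lessen the cyclic-discontinuity edge effects incurred when each
#' scale's power series is later phase-randomized (phase randomization treats
#' the series as circular).
#'
#' Two tolerance conventions are supported. The default, `ref = "first"`,
#' reads "within `tol_frac` of `x[1]`" literally: the tolerance is
#' `tol_frac * |x[1]|` (plus a `1e-15 * range` floor so signals that start at
#' numerical zero can still match an exactly-zero tail). `ref = "range"`
#' measures the tolerance against the signal's peak-to-peak range instead.
#' Strongly monotonous signals (e.g. an exponential ramp) have no late
#' near-recurrence of their first value, so clipping rejects them: that class
#' of signal is outside the test's domain.
#'
#' @param sig an [ispc_signal].
#' @param tol_frac tolerance fraction in (0, 1); default 0.01.
#' @param ref `"first"` (tolerance relative to `|x[1]|`, default) or
#'   `"range"` (relative to peak-to-peak range).
#' @param min_frac minimum retained fraction of the input length; if the
#'   clipped segment is shorter the signal is rejected (condition
#'   `ispct_no_clip_point`), since a continuous wavelet transform of a short
#'   remnant is meaningless.
#' @return the clipped, zero-meaned [ispc_signal].
#' @export
clip_to_cycle <- function(sig, tol_frac = 0.01, ref = c("first", "range"),
                          min_frac = 0.5) {
  stopifnot(inherits(sig, "ispc_signal"))
  ref <- match.arg(ref)
  if (!is.numeric(tol_frac) || tol_frac <= 0 || tol_frac >= 1) {
    ispct_stop("invalid_params", "`tol_frac` must be in (0, 1)")
  }
  x <- sig$samples
  rng <- max(x) - min(x)
  tol <- if (ref == "range") tol_frac * rng else tol_frac * abs(x[1]) + 1e-15 * rng
  hits <- which(abs(x - x[1]) <= tol)
  k2 <- hits[length(hits)] # x[1] always qualifies, so `hits` is never empty
  if (k2 < max(2, ceiling(min_frac * sig$n))) {
    ispct_stop(
      "no_clip_point",
      sprintf(paste0(
        "no late sample recurs near x[1] (last match at index %d of %d); ",
        "the clipped segment would be too short to decompose. ",
        "Strongly monotonous signals are unsupported."), k2, sig$n),
      k2 = k2, n = sig$n
    )
  }
  y <- x[seq_len(k2)]
  ispc_signal(y - mean(y), sig$fs, meta = sig$meta)
}

#' Shorten a signal to a standard duration bucket
#'
#' Long recordings are truncated (from the end) to the largest bucket duration
#' they cover, so that one cached white-noise null per bucket can be reused
#' across many recordings. With the default buckets, durations >= 500 s map to
#' 500 s, [400, 500) to 400 s and [350, 400) to 350 s.
#'
#' @param sig an [ispc_signal].
#' @param buckets increasing numeric vector of bucket durations in seconds.
#' @param strict if `TRUE`, a signal shorter than `min(buckets)` raises
#'   condition `ispct_too_short`; if `FALSE` (default, appropriate for short
#'   synthetic signals) it passes through unchanged.
#' @return an [ispc_signal] whose duration equals a bucket, or the input.
#' @export
standardize_length <- function(sig, buckets = c(350, 400, 500), strict = FALSE) {
  stopifnot(inherits(sig, "ispc_signal"), is.numeric(buckets), length(buckets) >= 1)
  buckets <- sort(buckets)
  dur <- sig$n / sig$fs
  if (dur < buckets[1]) {
    if (strict) {
      ispct_stop("too_short", sprintf(
        "signal duration %.4g s is below the smallest bucket (%g s)",
        dur, buckets[1]))
    }
    return(sig)
  }
  b <- max(buckets[buckets <= dur])
  n_new <- as.integer(round(sig$fs * b))
  ispc_signal(sig$samples[seq_len(n_new)], sig$fs, meta = sig$meta)
}

#' Diagnostic pre-checks for the inter-scale correlation test
#'
#' Reports (rather than enforces) the conditions a signal must meet for the
#' test to apply: finite samples, finite energy (proxies for Fourier
#' transformability), and existence of a clip point. Only reporting: callers
#' decide what to do with flags.
#'
#' @param sig an [ispc_signal].
#' @param tol_frac,ref,min_frac forwarded to [clip_to_cycle()].
#' @return a list of class `ispc_diagnostics` with logical fields
#'   `finite`, `finite_energy`, `clip_point`, the overall `ok`, and details.
#' @export
check_preconditions <- function(sig, tol_frac = 0.01, ref = c("first", "range"),
                                min_frac = 0.5) {
  ref <- match.arg(ref)
  finite <- is.list(sig) && is.numeric(sig$samples) && all(is.finite(sig$samples))
  energy <- if (finite) sum(sig$samples^2) else Inf
  finite_energy <- is.finite(energy)
  clip_ok <- FALSE
  clip_msg <- NA_character_
  if (finite) {
    res <- tryCatch(clip_to_cycle(sig, tol_frac, ref, min_frac),
                    ispct_error = function(e) e)
    if (inherits(res, "ispc_signal")) clip_ok <- TRUE else clip_msg <- conditionMessage(res)
  }
  structure(
    list(finite = finite, finite_energy = finite_energy, clip_point = clip_ok,
         clip_message = clip_msg, energy = energy, n = if (is.list(sig)) sig$n else NA,
         ok = finite && finite_energy && clip_ok),
    class = "ispc_diagnostics"
  )
}

#' @export
print.ispc_diagnostics <- function(x, ...) {
  flag <- function(b) if (isTRUE(b)) "pass" else "FAIL"
  cat("<ispc_diagnostics>\n")
  cat(sprintf("  finite samples : %s\n", flag(x$finite)))
  cat(sprintf("  finite energy  : %s\n", flag(x$finite_energy)))
  cat(sprintf("  clip point     : %s%s\n", flag(x$clip_point),
              if (!x$clip_point && !is.na(x$clip_message))
                paste0("  (", x$clip_message, ")") else ""))
  invisible(x)
}
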