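#' Standardized inter-scale correlation test statistics
#'
#' `T[a,b] = (r[a,b] - mean[a,b]) / sqrt(var[a,b])`, standardizing each
#' measured correlation by its normal null. Pairs with zero null variance
#' cannot be standardized; they are set to `NA` ("untested", never
#' "non-significant") and a warning of class `ispct_zero_variance` is raised.
#' The diagonal is `NA` by construction.
#'
#' @param ispcm an `ispcm` from [pearson_ispcm()].
#' @param null an `ispc_null` from [combine_null()] on the same grid.
#' @return symmetric numeric matrix of statistics with `NA` diagonal;
#'   attribute `untested` holds the indices of zero-variance pairs.
#' @export
test_statistics <- function(ispcm, null) {
  stopifnot(inherits(ispcm, "ispcm"), inherits(null, "ispc_null"))
  if (length(ispcm$freqs) != length(null$freqs) ||
      any(abs(ispcm$freqs - null$freqs) > 1e-9 * null$freqs)) {
    ispct_stop("grid_mismatch", "correlation matrix and null are on different scale grids")
  }
  va <- null$var
  zero <- which(!is.na(va) & va <= 0)
  if (length(zero)) {
    ispct_warn("zero_variance", sprintf(
      "%d pair(s) have zero null variance and are reported as untested",
      length(zero) / 2))
    va[zero] <- NA_real_
  }
  T <- (ispcm$r - null$mean) / sqrt(va)
  dimnames(T) <- dimnames(ispcm$r)
  attr(T, "untested") <- zero
  T
}

#' Cai-Liu FDR threshold for dependent correlation statistics
#'
#' Implements the data-driven rejection threshold for a family of
#' asymptotically standard-normal statistics `T[a,b]`, `a < b`, over `u`
#' scales: the smallest `t` in `[0, d_u]`, `d_u = sqrt(4 log u - 2 log(log
#' u))` (natural logarithms), such that
#' `G(t) * (u^2 - u)/2 / max(R(t), 1) <= alpha`, where `G(t) = 2 - 2 Phi(t)`
#' and `R(t)` counts statistics with `|T| >= t`. If no such `t` exists the
#' fallback `t_hat = 2 sqrt(log u)` is used. Since `G` is continuous and
#' monotone and `R` only changes at observed `|T|` values, the criterion is
#' evaluated exactly on the candidate grid `{0} U sorted |T| U {d_u}`; the
#' rejection set is identical to the one from the continuous infimum.
#'
#' @param T symmetric matrix of standardized statistics (`NA` entries — the
#'   diagonal and any untested pairs — are ignored), or a vector of
#'   upper-triangle statistics together with `u`.
#' @param alpha FDR level in (0, 1).
#' @param u number of scales; required only when `T` is a vector.
#' @param tail `"two.sided"` (default; reject `|T| >= t_hat`, null tail
#'   probability `G(t) = 2 - 2 Phi(t)`) or `"greater"` (reject `T >= t_hat`,
#'   `G(t) = 1 - Phi(t)`; tests only whether correlations exceed the null,
#'   appropriate when the null mean is deliberately conservative).
#' @return list with `t_hat`, `mask` (symmetric logical matrix of rejected
#'   pairs, `FALSE` diagonal; only when `T` is a matrix), `n_significant`
#'   (rejected pairs, counted once), `used_fallback`, `alpha`, `u`, `d_u`.
#' @export
cai_liu_threshold <- function(T, alpha, u = NULL,
                              tail = c("two.sided", "greater")) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    ispct_stop("invalid_alpha", "`alpha` must be a single value in (0, 1)")
  }
  tail <- match.arg(tail)
  is_mat <- is.matrix(T)
  stat <- function(v) if (tail == "two.sided") abs(v) else v
  if (is_mat) {
    u <- ncol(T)
    tvals <- stat(T[upper.tri(T)])
  } else {
    if (is.null(u)) ispct_stop("invalid_params", "`u` is required when `T` is a vector")
    tvals <- stat(as.numeric(T))
  }
  if (u < 2) ispct_stop("invalid_params", "need at least 2 scales")
  tvals <- tvals[!is.na(tvals)]
  n_hyp <- u * (u - 1) / 2
  d_u <- sqrt(4 * log(u) - 2 * log(log(u)))
  cand <- sort(unique(c(0, tvals[tvals >= 0 & tvals <= d_u], d_u)))
  # R(t) and the FDR criterion on the candidate grid
  Rt <- vapply(cand, function(t) sum(tvals >= t), numeric(1))
  Gt <- if (tail == "two.sided") 2 - 2 * stats::pnorm(cand) else 1 - stats::pnorm(cand)
  crit <- Gt * n_hyp / pmax(Rt, 1)
  ok <- which(crit <= alpha)
  if (length(ok)) {
    t_hat <- cand[ok[1]]
    used_fallback <- FALSE
  } else {
    t_hat <- 2 * sqrt(log(u))
    used_fallback <- TRUE
  }
  out <- list(t_hat = t_hat, alpha = alpha, u = u, d_u = d_u,
              tail = tail, used_fallback = used_fallback)
  if (is_mat) {
    mask <- !is.na(T) & stat(T) >= t_hat
    mask <- mask | t(mask)
    diag(mask) <- FALSE
    out$mask <- mask
    out$n_significant <- sum(mask[upper.tri(mask)])
  } else {
    out$n_significant <- sum(tvals >= t_hat)
  }
  out
}

#' Count the main groupings of a significance mask
#'
#' Significant inter-scale pairs typically occur in contiguous clusters
#' ("groupings") of the correlation matrix. This counts the 8-connected
#' components of the boolean mask whose cell count is at least
#' `min_area_frac * u^2`, ignoring scattered sub-threshold debris.
#'
#' Pairs within a few scales of the diagonal are untestable by construction
#' (the conservative null mean there exceeds 1), so a grouping centred
#' \emph{on} the diagonal appears as two mirror-image components separated
#' by a thin unrejectable corridor. With `diag_gap > 0`, a component that
#' reaches within `diag_gap` cells of the diagonal is merged with its mirror
#' twin and the pair counts (and is sized) as one diagonal-centred grouping;
#' symmetric twins far from the diagonal (genuine cross-frequency
#' groupings) remain two. Set `diag_gap = 0` for plain connected-component
#' counting.
#'
#' @param mask symmetric logical matrix (diagonal ignored).
#' @param min_area_frac minimum grouping size as a fraction of `u^2`;
#'   default 0.005.
#' @param diag_gap corridor half-width (in scales) for diagonal bridging;
#'   default 5 (half an octave at the default 10 voices per octave).
#' @return integer count; attribute `sizes` holds all grouping sizes (after
#'   merging), in decreasing order.
#' @export
count_main_groupings <- function(mask, min_area_frac = 0.005, diag_gap = 5L) {
  stopifnot(is.matrix(mask), is.logical(mask), nrow(mask) == ncol(mask))
  u <- nrow(mask)
  diag(mask) <- FALSE
  cells <- which(mask, arr.ind = TRUE)
  if (!nrow(cells)) {
    return(structure(0L, sizes = integer(0)))
  }
  id <- (cells[, 2] - 1L) * u + cells[, 1] # linear index
  pos <- integer(u * u); pos[id] <- seq_along(id)
  # 8-neighbour adjacency in linear indexing (guarding matrix bounds)
  edges <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r2 <- cells[, 1] + dr; c2 <- cells[, 2] + dc
    valid <- r2 >= 1 & r2 <= u & c2 >= 1 & c2 <= u
    nb <- pos[(c2[valid] - 1L) * u + r2[valid]]
    from <- which(valid)[nb > 0]
    if (length(from)) edges <- c(edges, rbind(from, nb[nb > 0]))
  }
  g <- igraph::make_graph(edges, n = length(id), directed = FALSE)
  memb <- igraph::components(g)$membership
  if (diag_gap > 0) {
    # bridge mirror twins across the unrejectable near-diagonal corridor
    near <- abs(cells[, 1] - cells[, 2]) <= diag_gap
    if (any(near)) {
      mirror <- memb[pos[(cells[near, 1] - 1L) * u + cells[near, 2]]]
      bridge <- unique(cbind(memb[near], mirror))
      gl <- igraph::make_graph(t(bridge), n = max(memb), directed = FALSE)
      relabel <- igraph::components(gl)$membership
      memb <- relabel[memb]
    }
  }
  sizes <- as.integer(table(memb))
  structure(sum(sizes >= min_area_frac * u^2), sizes = sort(sizes, decreasing = TRUE))
}

#' Full configuration for the inter-scale correlation test
#'
#' @param alpha FDR level, default 0.01.
#' @param L white-noise Monte Carlo iterations, default 1000 (use 250 for the
#'   synthetic validation settings).
#' @param H phase-randomization Monte Carlo iterations, default 250 (150 for
#'   the synthetic validation settings).
#' @param wavelet a [morse_params()].
#' @param surrogate_method `"ft"` or `"iaaft"`.
#' @param surrogate_scope `"scale"` (randomize each scale's power series,
#'   default) or `"signal"` (whole-signal surrogates re-decomposed through
#'   the transform); see [phase_rand_null()].
#' @param tail rejection tail for [cai_liu_threshold()]; `"two.sided"`
#'   (default) or `"greater"`.
#' @param coi_min_frac COI retention threshold, default 0.9.
#' @param clip_tol,clip_ref,clip_min_frac clipping controls, see
#'   [clip_to_cycle()].
#' @param noise_kind white-noise flavour for the oversampling null.
#' @param length_buckets standard-length buckets in seconds, or `NULL`
#'   (default) to skip length standardization (appropriate for synthetic
#'   signals).
#' @param seed root seed; all Monte Carlo stages derive their seeds from it.
#' @param fft_friendly_window shrink the correlation window to the nearest
#'   5-smooth length (at most a fraction of a percent of samples) so
#'   surrogate FFTs avoid slow prime lengths; default `TRUE`.
#' @param null_cache_dir optional directory for caching white-noise nulls
#'   across runs with identical (length, rate, wavelet, L, seed) keys.
#' @param normality_check if `TRUE`, attach [normality_diagnostics()] of the
#'   phase-randomization null to the result.
#' @return list of class `ispc_config`.
#' @export
ispc_config <- function(alpha = 0.01, L = 1000, H = 250,
                        wavelet = morse_params(),
                        surrogate_method = c("ft", "iaaft"),
                        surrogate_scope = c("scale", "signal"),
                        tail = c("two.sided", "greater"),
                        coi_min_frac = 0.9,
                        clip_tol = 0.01, clip_ref = c("first", "range"),
                        clip_min_frac = 0.5,
                        noise_kind = c("gaussian", "uniform"),
                        length_buckets = NULL,
                        seed = 1,
                        fft_friendly_window = TRUE,
                        null_cache_dir = NULL,
                        normality_check = FALSE) {
  if (alpha <= 0 || alpha >= 1) ispct_stop("invalid_alpha", "`alpha` must be in (0, 1)")
  if (L < 2 || H < 2) ispct_stop("invalid_params", "`L` and `H` must be >= 2")
  structure(
    list(alpha = alpha, L = L, H = H, wavelet = wavelet,
         surrogate_method = match.arg(surrogate_method),
         surrogate_scope = match.arg(surrogate_scope),
         tail = match.arg(tail),
         coi_min_frac = coi_min_frac,
         clip_tol = clip_tol, clip_ref = match.arg(clip_ref),
         clip_min_frac = clip_min_frac,
         noise_kind = match.arg(noise_kind),
         length_buckets = length_buckets, seed = seed,
         fft_friendly_window = fft_friendly_window,
         null_cache_dir = null_cache_dir,
         normality_check = normality_check),
    class = "ispc_config"
  )
}

#' Run the full inter-scale power correlation significance test
#'
#' Executes the whole pipeline on one signal: clip to a near-cycle (and
#' optionally standardize the length), wavelet-decompose, form the power
#' spectrum, filter against the cone of influence, compute the inter-scale
#' Pearson matrix, build the two-element Monte Carlo null (white-noise
#' frequency-oversampling mean + phase-randomization spread), standardize,
#' and threshold with the Cai-Liu FDR procedure.
#'
#' @param sig an [ispc_signal].
#' @param config an [ispc_config()].
#' @return object of class `ispc_test`: list with `ispcm`, `null`,
#'   `statistics` (matrix `T`), `t_hat`, `mask`, `n_significant`,
#'   `used_fallback`, `alpha`, `u`, `config`, `stages` (per-stage metadata),
#'   and optionally `normality`.
#' @export
run_ispc_test <- function(sig, config = ispc_config()) {
  stopifnot(inherits(sig, "ispc_signal"), inherits(config, "ispc_config"))
  clipped <- clip_to_cycle(sig, tol_frac = config$clip_tol,
                           ref = config$clip_ref,
                           min_frac = config$clip_min_frac)
  if (!is.null(config$length_buckets)) {
    clipped <- standardize_length(clipped, buckets = config$length_buckets)
  }
  cw <- morse_cwt(clipped, config$wavelet)
  wps <- compute_wps(cw)
  tw <- coi_trim(wps, config$coi_min_frac)
  if (isTRUE(config$fft_friendly_window)) {
    m <- ncol(tw$power)
    m2 <- largest_5smooth(m)
    if (m2 < m) {
      tw$power <- tw$power[, seq_len(m2), drop = FALSE]
      tw$time_window[2] <- tw$time_window[1] + m2 - 1L
    }
  }
  ispcm <- pearson_ispcm(tw)
  if (length(ispcm$dropped_scales)) {
    # degenerate scales would desynchronize the null grid; refuse rather than guess
    ispct_stop("degenerate_scale",
               "degenerate (zero-variance) scales present; cannot align null grid")
  }
  wn <- get_white_noise_null(
    n = clipped$n, fs = clipped$fs, params = config$wavelet, L = config$L,
    noise_kind = config$noise_kind, seed = derive_seed(config$seed, "wn_root"),
    min_in_coi_frac = config$coi_min_frac, window = as.integer(tw$time_window),
    cache_dir = config$null_cache_dir)
  pr <- phase_rand_null(tw, H = config$H, method = config$surrogate_method,
                        seed = derive_seed(config$seed, "pr_root"),
                        scope = config$surrogate_scope, sig = clipped)
  null <- combine_null(wn, pr)
  T <- test_statistics(ispcm, null)
  cl <- cai_liu_threshold(T, config$alpha, tail = config$tail)
  out <- list(
    ispcm = ispcm, null = null, statistics = T,
    t_hat = cl$t_hat, mask = cl$mask, n_significant = cl$n_significant,
    used_fallback = cl$used_fallback, alpha = config$alpha, u = cl$u,
    d_u = cl$d_u, config = config,
    stages = list(n_input = sig$n, n_clipped = clipped$n,
                  time_window = tw$time_window,
                  retained_freqs = tw$retained_freqs,
                  seed = config$seed)
  )
  if (isTRUE(config$normality_check)) out$normality <- normality_diagnostics(pr)
  structure(out, class = "ispc_test")
}

#' @export
print.ispc_test <- function(x, ...) {
  cat(sprintf("<ispc_test> u = %d scales (%.4g-%.4g Hz), alpha = %g\n",
              x$u, min(x$null$freqs), max(x$null$freqs), x$alpha))
  cat(sprintf("  t_hat = %.4f%s; %d of %d pairs significant\n",
              x$t_hat, if (x$used_fallback) " (fallback 2*sqrt(log u))" else "",
              x$n_significant, x$u * (x$u - 1) / 2))
  ng <- count_main_groupings(x$mask)
  cat(sprintf("  main groupings (>= 0.5%% of matrix area): %d\n", as.integer(ng)))
  invisible(x)
}

#' Heatmap of a significance-masked correlation matrix
#'
#' Displays the inter-scale correlation matrix on logarithmic frequency axes
#' with non-significant cells blacked out.
#'
#' @param x an `ispc_test`.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.ispc_test <- function(x, ...) {
  r <- x$ispcm$r
  r[!x$mask] <- NA
  f <- x$ispcm$freqs
  idx <- order(f)
  graphics::image(log10(f[idx]), log10(f[idx]), r[idx, idx],
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  zlim = c(-1, 1), xlab = "log10 frequency (Hz)",
                  ylab = "log10 frequency (Hz)", useRaster = TRUE, ...)
  invisible(x)
}
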