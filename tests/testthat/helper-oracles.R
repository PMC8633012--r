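# Independent brute-force oracles used to validate the fast implementations.
# These deliberately avoid the code paths they check.

# Naive two-loop Pearson correlation matrix of the rows of `power`.
naive_ispcm <- function(power) {
  u <- nrow(power)
  r <- matrix(NA_real_, u, u)
  for (a in seq_len(u)) {
    for (b in seq_len(u)) {
      sa <- power[a, ]; sb <- power[b, ]
      da <- sa - mean(sa); db <- sb - mean(sb)
      r[a, b] <- sum(da * db) / (sqrt(sum(da^2)) * sqrt(sum(db^2)))
    }
  }
  r
}

# Brute-force clip point: scan indices from the end for the last sample
# within `tol` of x[1].
brute_clip_index <- function(x, tol) {
  for (k in rev(seq_along(x))) {
    if (abs(x[k] - x[1]) <= tol) return(k)
  }
  NA_integer_
}

# Brute-force Cai-Liu threshold: evaluate the FDR criterion on the full
# candidate grid {0} U sorted |T| U {d_u} by direct summation.
brute_cai_liu <- function(tvals, u, alpha) {
  tvals <- abs(tvals[!is.na(tvals)])
  d_u <- sqrt(4 * log(u) - 2 * log(log(u)))
  n_hyp <- u * (u - 1) / 2
  grid <- sort(unique(c(0, tvals[tvals <= d_u], d_u)))
  for (t in grid) {
    R <- 0
    for (v in tvals) if (v >= t) R <- R + 1
    G <- 2 - 2 * pnorm(t)
    if (G * n_hyp / max(R, 1) <= alpha) {
      return(list(t_hat = t, used_fallback = FALSE))
    }
  }
  list(t_hat = 2 * sqrt(log(u)), used_fallback = TRUE)
}

# Brute-force flood fill: count 8-connected components of a logical matrix
# with at least `min_cells` cells.
flood_fill_count <- function(mask, min_cells) {
  u <- nrow(mask)
  seen <- matrix(FALSE, u, ncol(mask))
  sizes <- integer(0)
  for (i in seq_len(u)) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || seen[i, j]) next
    stack <- list(c(i, j)); seen[i, j] <- TRUE; size <- 0L
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- cur[1] + dr; c2 <- cur[2] + dc
        if (r2 >= 1 && r2 <= u && c2 >= 1 && c2 <= ncol(mask) &&
            mask[r2, c2] && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          stack[[length(stack) + 1L]] <- c(r2, c2)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sum(sizes >= min_cells)
}

# FFT-based analytic signal, for instantaneous-frequency checks of chirps.
inst_freq <- function(x, fs) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n); h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else h[2:((n + 1) / 2)] <- 2
  z <- fft(X * h, inverse = TRUE) / n
  ph <- Arg(z)
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi # unwrap increments
  dph * fs / (2 * pi)
}

# Small trimmed-power-spectrum stub for unit tests that exercise the
# correlation and null machinery without a full decomposition.
make_tw <- function(power, freqs = NULL, fs = 100) {
  u <- nrow(power)
  structure(
    list(power = power,
         retained_freqs = if (is.null(freqs)) 2^seq(u, 1) else freqs,
         retained_scales = seq_len(u),
         time_window = c(1L, ncol(power)),
         fs = fs, n_original = ncol(power), params = morse_params(),
         min_in_coi_frac = 0.9),
    class = "ispc_wps_trimmed"
  )
}

# Deterministic small signals for pipeline tests: short enough to keep the
# Monte Carlo cheap, long enough for a few octaves of scales.
small_noise_sig <- function(n = 3000, fs = 200, seed = 5) {
  ispc_signal(with_seed(seed, rnorm(n)), fs, meta = "unit_noise")
}
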