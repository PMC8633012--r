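#' @keywords internal
"_PACKAGE"

# Classed conditions: every error raised by the package carries a class of the
# form "ispct_<what>" so callers (and the CLI) can map failures to stages.
ispct_stop <- function(class, msg, call = sys.call(-1), ...) {
  stop(structure(
    class = c(paste0("ispct_", class), "ispct_error", "error", "condition"),
    list(message = msg, call = call, ...)
  ))
}

ispct_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(paste0("ispct_", class), "ispct_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Derive a reproducible per-stage, per-iteration seed from a root seed
#'
#' Monte Carlo loops draw their randomness through seeds derived from a single
#' root seed, so that iterations are independent of execution order and a run
#' is fully reconstructable from its summary. The derivation is a fixed
#' integer mix computed in double precision and reduced mod 2^31 - 1.
#'
#' @param root integer root seed.
#' @param stage character stage label (e.g. `"white_noise"`, `"phase_rand"`).
#' @param i iteration index (>= 0).
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, stage, i = 0L) {
  stopifnot(is.numeric(root), length(root) == 1L, is.finite(root))
  m <- 2147483647 # 2^31 - 1
  h <- sum(utf8ToInt(as.character(stage)) * 257^(seq_along(utf8ToInt(as.character(stage))) %% 7)) %% m
  v <- (abs(root) %% m)
  v <- (v * 48271) %% m
  v <- (v + h) %% m
  v <- (v * 69621 + as.numeric(i) * 7919 + 1) %% m
  as.integer(v %% (m - 1) + 1)
}

# Largest 5-smooth integer (only prime factors 2, 3, 5) <= n. Used to shave a
# handful of samples off an analysis window so that surrogate FFTs of that
# length stay in the fast mixed-radix regime.
largest_5smooth <- function(n) {
  stopifnot(n >= 1)
  best <- 1
  p2 <- 1
  while (p2 <= n) {
    p23 <- p2
    while (p23 <= n) {
      p235 <- p23
      while (p235 <= n) {
        if (p235 > best) best <- p235
        p235 <- p235 * 5
      }
      p23 <- p23 * 3
    }
    p2 <- p2 * 2
  }
  best
}

# Smallest 5-smooth integer >= n: FFT-friendly transform length.
next_5smooth <- function(n) {
  stopifnot(n >= 1)
  best <- Inf
  p2 <- 1
  while (p2 < 2 * n) {
    p23 <- p2
    while (p23 < 2 * n) {
      p235 <- p23
      while (p235 < n) p235 <- p235 * 5
      if (p235 < best) best <- p235
      p23 <- p23 * 3
    }
    p2 <- p2 * 2
  }
  best
}

# Pearson correlation matrix of the columns of `m` via a single BLAS
# cross-product and the moment identity sum((x-xbar)(y-ybar)) =
# sum(xy) - n*xbar*ybar. Much faster than stats::cor for wide matrices
# (no large centered temporaries); zero-variance columns yield NA entries
# (callers decide how to treat them).
fast_cor <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  C <- crossprod(m) / n - tcrossprod(mu)
  v <- diag(C)
  zero <- v <= 0
  s <- sqrt(pmax(v, 0))
  s[zero] <- 1
  r <- C / tcrossprod(s)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  if (any(zero)) {
    r[zero, ] <- NA_real_
    r[, zero] <- NA_real_
  }
  r
}

# Evaluate a function with a temporarily-seeded RNG, restoring (or removing)
# the global .Random.seed afterwards so library code does not disturb user
# RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
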