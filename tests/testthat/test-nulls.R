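# Small problem sizes throughout: a 16-20 s signal at 200-250 Hz gives
# ~5 octaves of retained scales, enough structure to exercise every property
# while keeping the Monte Carlo cheap.

test_that("white-noise mean matrix has the oversampling-bias structure", {
  wn <- white_noise_mean_ispcm(n = 4000, fs = 200, L = 200, seed = 3)
  r <- wn$rho_bar
  expect_identical(unname(diag(r)), rep(1, nrow(r)))
  expect_equal(r, t(r))
  expect_true(all(r >= -1 & r <= 1))
  lf <- log2(wn$freqs)
  sep <- abs(outer(lf, lf, `-`))
  # pairs >= 4 octaves apart: asymptotically uncorrelated
  expect_lt(max(abs(r[sep >= 4])), 0.05)
  # immediately adjacent scales: strong intrinsic overlap correlation
  adj <- row(r) == col(r) + 1
  expect_gt(min(r[adj]), 0.5)
})

test_that("white-noise null is deterministic and respects its window argument", {
  a <- white_noise_mean_ispcm(n = 2000, fs = 200, L = 20, seed = 9)
  b <- white_noise_mean_ispcm(n = 2000, fs = 200, L = 20, seed = 9)
  expect_identical(a$rho_bar, b$rho_bar)
  c <- white_noise_mean_ispcm(n = 2000, fs = 200, L = 20, seed = 10)
  expect_false(identical(a$rho_bar, c$rho_bar))
  expect_error(
    white_noise_mean_ispcm(n = 2000, fs = 200, L = 20, seed = 1,
                           window = c(1L, 2000L)),
    class = "ispct_invalid_params") # window outside the fully-in-COI span
})

test_that("phase-randomization null is centred at zero with bounded samples", {
  sig <- small_noise_sig(n = 4000, fs = 250, seed = 6)
  tw <- coi_trim(compute_wps(morse_cwt(sig)))
  pr <- phase_rand_null(tw, H = 80, seed = 4)
  expect_true(all(pr$samples >= -1 & pr$samples <= 1))
  up <- upper.tri(pr$phi_bar)
  # off-diagonal means are zero within 3 SD / sqrt(H)
  z <- abs(pr$phi_bar[up]) / (sqrt(pr$phi_var[up]) / sqrt(pr$H))
  expect_lt(mean(z > 3), 0.02)
  expect_equal(pr$phi_bar, t(pr$phi_bar))
  expect_true(all(pr$phi_var[up] > 0))
})

test_that("null correlations match a brute-force two-surrogate construction", {
  # the pipeline randomizes all scales jointly; the oracle builds a pair of
  # independent surrogates by hand. Same distribution => KS non-rejection.
  sig <- small_noise_sig(n = 2500, fs = 250, seed = 16)
  tw <- coi_trim(compute_wps(morse_cwt(sig)))
  a <- 1; b <- nrow(tw$power) %/% 2
  pr <- phase_rand_null(tw, H = 120, seed = 8)
  u <- nrow(tw$power)
  pair_col <- which(which(upper.tri(matrix(0, u, u))) ==
                      (b - 1) * u + a)
  impl <- pr$samples[, pair_col]
  oracle <- vapply(seq_len(120), function(h) {
    sa <- ft_phase_randomize(tw$power[a, ], seed = 1000 + h)
    sb <- ft_phase_randomize(tw$power[b, ], seed = 5000 + h)
    stats::cor(sa, sb)
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(impl, oracle)$p.value), 0.05)
})

test_that("longer windows tighten the phase-randomization null", {
  mkvar <- function(n) {
    sig <- small_noise_sig(n = n, fs = 250, seed = 31)
    tw <- coi_trim(compute_wps(morse_cwt(sig)))
    pr <- phase_rand_null(tw, H = 60, seed = 2)
    # compare over the scale grid common to both lengths (highest scales)
    stats::median(pr$phi_var[upper.tri(pr$phi_var)][seq_len(200)])
  }
  expect_lt(mkvar(6000), mkvar(2000))
})

test_that("combining the null elements is elementwise and grid-checked", {
  u <- 3
  freqs <- c(40, 20, 10)
  rho <- matrix(c(1, .6, .1, .6, 1, .5, .1, .5, 1), u, u)
  phib <- matrix(c(1, .02, -.01, .02, 1, .03, -.01, .03, 1), u, u)
  phiv <- matrix(c(0, .004, .002, .004, 0, .003, .002, .003, 0), u, u)
  wn <- structure(list(rho_bar = rho, freqs = freqs, L = 10,
                       noise_kind = "gaussian", seed = 1, n = 100, fs = 10,
                       window = c(1, 100)), class = "wn_null")
  pr <- structure(list(phi_bar = phib, phi_var = phiv, H = 20, method = "ft",
                       seed = 2, freqs = freqs), class = "pr_null")
  nm <- combine_null(wn, pr)
  expect_equal(nm$mean[1, 2], .6 + .02)
  expect_equal(nm$mean[1, 3], .1 - .01)
  expect_equal(nm$var[2, 3], .003)
  expect_true(all(is.na(diag(nm$mean)))) # self-pairs excluded from testing
  # zero white-noise bias: combined mean reduces to the phase-randomized mean
  wn0 <- wn; wn0$rho_bar <- diag(u)
  off <- !diag(u)
  expect_equal(combine_null(wn0, pr)$mean[off], phib[off])
  pr2 <- pr; pr2$freqs <- c(40, 20, 11)
  expect_error(combine_null(wn, pr2), class = "ispct_grid_mismatch")
})

test_that("normality diagnostics are calibrated and detect skew", {
  mkpr <- function(samples) {
    structure(list(samples = samples, H = nrow(samples), method = "ft",
                   phi_bar = NULL, phi_var = NULL, freqs = NULL),
              class = "pr_null")
  }
  norm_s <- matrix(with_seed(1, rnorm(150 * 200)), 150, 200)
  rep1 <- normality_diagnostics(mkpr(norm_s))
  expect_gte(rep1$pass_fraction, 1 - rep1$alpha - 0.05)
  expect_identical(rep1$H, 150L)
  skew_s <- matrix(with_seed(2, rexp(150 * 200)), 150, 200)
  rep2 <- normality_diagnostics(mkpr(skew_s))
  expect_lt(rep2$pass_fraction, 0.2)
  expect_error(normality_diagnostics(mkpr(norm_s), alpha = 2),
               class = "ispct_invalid_alpha")
})

test_that("whole-signal surrogates keep overlap correlation, power surrogates do not", {
  sig <- small_noise_sig(n = 3000, fs = 250, seed = 41)
  tw <- coi_trim(compute_wps(morse_cwt(sig)))
  pr_sc <- phase_rand_null(tw, H = 40, seed = 5, scope = "scale")
  pr_si <- phase_rand_null(tw, H = 40, seed = 5, scope = "signal", sig = sig)
  adj <- row(pr_sc$phi_bar) == col(pr_sc$phi_bar) + 1
  # per-scale randomization destroys all cross-scale alignment: mean ~ 0
  expect_lt(max(abs(pr_sc$phi_bar[adj])), 0.2)
  # whole-signal surrogates share band overlap: adjacent means stay strong
  expect_gt(min(pr_si$phi_bar[adj]), 0.5)
  expect_true(all(pr_si$samples >= -1 & pr_si$samples <= 1))
  # determinism and the required signal argument
  pr_si2 <- phase_rand_null(tw, H = 40, seed = 5, scope = "signal", sig = sig)
  expect_identical(pr_si$samples, pr_si2$samples)
  expect_error(phase_rand_null(tw, H = 10, scope = "signal"),
               class = "ispct_invalid_params")
})
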