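make_null <- function(mean_m, var_m, freqs) {
  diag(mean_m) <- NA_real_; diag(var_m) <- NA_real_
  structure(list(mean = mean_m, var = var_m, freqs = freqs,
                 provenance = list()), class = "ispc_null")
}

make_ispcm <- function(r, freqs) {
  structure(list(r = r, freqs = freqs, n_used = 100L,
                 dropped_scales = integer(0)), class = "ispcm")
}

test_that("standardization of correlations against the null is exact", {
  freqs <- c(8, 4, 2)
  r <- matrix(1, 3, 3)
  r[1, 2] <- r[2, 1] <- 0.30
  r[1, 3] <- r[3, 1] <- 0.15
  r[2, 3] <- r[3, 2] <- 0.10 + 0.05 # mean + 1 sd below
  mu <- matrix(0.10, 3, 3)
  va <- matrix(0.0025, 3, 3)
  T <- test_statistics(make_ispcm(r, freqs), make_null(mu, va, freqs))
  expect_equal(T[1, 2], 4)            # (0.30 - 0.10) / 0.05
  expect_equal(T[2, 3], 1)            # one SD above the mean
  expect_equal(T[1, 3], 1)
  expect_true(all(is.na(diag(T))))
  # r equal to the null mean gives T = 0
  T0 <- test_statistics(make_ispcm(mu + diag(0.9, 3), freqs),
                        make_null(mu, va, freqs))
  expect_equal(T0[1, 2], 0)
  # zero-variance pairs are untested, with a warning
  va2 <- va; va2[1, 2] <- va2[2, 1] <- 0
  expect_warning(
    T2 <- test_statistics(make_ispcm(r, freqs), make_null(mu, va2, freqs)),
    class = "ispct_zero_variance")
  expect_true(is.na(T2[1, 2]))
  expect_false(is.na(T2[1, 3]))
})

test_that("threshold search matches the brute-force oracle on random instances", {
  for (seed in 1:6) {
    u <- c(10, 25, 50, 80, 25, 40)[seed]
    tv <- with_seed(seed, rnorm(u * (u - 1) / 2, sd = 1 + seed / 6))
    alpha <- c(0.05, 0.01, 0.1, 0.05, 0.2, 0.001)[seed]
    got <- cai_liu_threshold(tv, alpha, u = u)
    want <- brute_cai_liu(tv, u, alpha)
    expect_equal(got$t_hat, want$t_hat)
    expect_identical(got$used_fallback, want$used_fallback)
  }
})

test_that("all-zero statistics trigger the fallback threshold and no rejections", {
  u <- 50
  T <- matrix(0, u, u); diag(T) <- NA
  out <- cai_liu_threshold(T, alpha = 0.05)
  expect_true(out$used_fallback)
  expect_equal(out$t_hat, 2 * sqrt(log(50)))
  expect_identical(out$n_significant, 0L)
  expect_equal(out$d_u, sqrt(4 * log(50) - 2 * log(log(50))))
})

test_that("strongly planted signals are all rejected", {
  u <- 50
  npair <- u * (u - 1) / 2
  tv <- with_seed(99, rnorm(npair))
  planted <- with_seed(100, sample(npair, 10))
  tv[planted] <- 8 * sign(tv[planted] + 0.1)
  T <- matrix(0, u, u)
  T[upper.tri(T)] <- tv
  T <- T + t(T); diag(T) <- NA
  out <- cai_liu_threshold(T, alpha = 0.01)
  idx <- which(upper.tri(T))[planted]
  expect_true(all(out$mask[idx]))
  expect_identical(out$n_significant, 10L) # and nothing else at this seed
  # and the threshold equals the brute-force scan
  expect_equal(out$t_hat, brute_cai_liu(tv, u, 0.01)$t_hat)
})

test_that("rejections are monotone in alpha and R(t) is non-increasing", {
  u <- 30
  tv <- with_seed(5, rnorm(u * (u - 1) / 2, sd = 1.4))
  alphas <- c(0.001, 0.005, 0.01, 0.05, 0.1, 0.2)
  ns <- sapply(alphas, function(a) cai_liu_threshold(tv, a, u = u)$n_significant)
  expect_true(all(diff(ns) >= 0))
  ths <- sapply(alphas, function(a) cai_liu_threshold(tv, a, u = u)$t_hat)
  expect_true(all(diff(ths) <= 0))
  expect_error(cai_liu_threshold(tv, 1.5, u = u), class = "ispct_invalid_alpha")
})

test_that("grouping counts agree with a brute-force flood fill", {
  u <- 40
  empty <- matrix(FALSE, u, u)
  expect_identical(as.integer(count_main_groupings(empty)), 0L)
  one <- empty; one[5:12, 5:12] <- TRUE
  expect_identical(as.integer(count_main_groupings(one)), 1L)
  # two blocks and scattered singletons below the area threshold
  two <- empty
  two[3:10, 3:10] <- TRUE
  two[25:32, 25:32] <- TRUE
  two[15, 38] <- two[38, 15] <- two[20, 2] <- two[2, 20] <- TRUE
  expect_identical(as.integer(count_main_groupings(two, 0.005)), 2L)
  min_cells <- ceiling(0.005 * u^2)
  expect_identical(as.integer(count_main_groupings(two, 0.005, diag_gap = 0)),
                   flood_fill_count(two, min_cells))
  # a diagonal-centred blob split by an unrejectable corridor counts once
  split <- matrix(FALSE, u, u)
  for (i in 5:14) for (j in 5:14) if (abs(i - j) >= 3) split[i, j] <- TRUE
  expect_identical(as.integer(count_main_groupings(split, 0.005, diag_gap = 0)), 2L)
  expect_identical(as.integer(count_main_groupings(split, 0.005, diag_gap = 5)), 1L)
  # ...but distant symmetric twins still count twice
  twins <- matrix(FALSE, u, u)
  twins[3:10, 25:32] <- TRUE; twins[25:32, 3:10] <- TRUE
  expect_identical(as.integer(count_main_groupings(twins, 0.005, diag_gap = 5)), 2L)
  # random masks against the oracle
  for (seed in 1:4) {
    m <- matrix(with_seed(seed, runif(u * u)) < 0.08, u, u)
    m <- m | t(m); diag(m) <- FALSE
    expect_identical(as.integer(count_main_groupings(m, 0.004, diag_gap = 0)),
                     flood_fill_count(m, ceiling(0.004 * u^2)))
  }
})

test_that("the full pipeline is deterministic and propagates stage errors", {
  sig <- small_noise_sig(n = 2500, fs = 250, seed = 19)
  cfg <- ispc_config(alpha = 0.05, L = 12, H = 12, seed = 7)
  r1 <- run_ispc_test(sig, cfg)
  r2 <- run_ispc_test(sig, cfg)
  expect_identical(r1$statistics, r2$statistics)
  expect_identical(r1$ispcm$r, r2$ispcm$r)
  expect_identical(r1$mask, r2$mask)
  # exponential input surfaces the clip-point error from preprocessing
  expect_error(run_ispc_test(gen_exponential(fs = 250, duration = 20), cfg),
               class = "ispct_no_clip_point")
})

test_that("run summaries serialize the scalars needed to reproduce a run", {
  sig <- gen_white_noise(fs = 200, duration = 10, kind = "uniform", seed = 23)
  sig$samples[sig$n] <- sig$samples[1] # guarantee a clip point at the very end
  cfg <- ispc_config(alpha = 0.05, L = 8, H = 8, seed = 3)
  res <- run_ispc_test(sig, cfg)
  tf <- withr::local_tempfile(fileext = ".json")
  write_run_summary(res, tf)
  s <- jsonlite::read_json(tf)
  expect_identical(s$u, res$u)
  expect_identical(s$config$seed, 3L)
  expect_equal(s$t_hat, res$t_hat)
})

test_that("one-sided thresholding rejects only the upper tail", {
  u <- 40
  npair <- u * (u - 1) / 2
  tv <- with_seed(55, rnorm(npair))
  hi <- 1:8; lo <- 9:16
  tv[hi] <- 8; tv[lo] <- -8
  two <- cai_liu_threshold(tv, 0.01, u = u)
  one <- cai_liu_threshold(tv, 0.01, u = u, tail = "greater")
  expect_identical(two$n_significant, 16L) # both tails
  expect_identical(one$n_significant, 8L)  # upper tail only
  # one-sided matches a direct one-sided grid scan
  d_u <- sqrt(4 * log(u) - 2 * log(log(u)))
  grid <- sort(unique(c(0, tv[tv >= 0 & tv <= d_u], d_u)))
  want <- 2 * sqrt(log(u)) # fallback when no grid point qualifies
  for (t in grid) {
    if ((1 - pnorm(t)) * npair / max(sum(tv >= t), 1) <= 0.01) { want <- t; break }
  }
  expect_equal(one$t_hat, want)
})
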