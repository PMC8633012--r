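test_that("generators are deterministic given a seed", {
  for (kind in c("double_sinusoid", "double_pulse", "double_chirp",
                 "square_wave", "exponential", "white_noise")) {
    a <- synth_signal(kind, fs = 200, duration = 5, seed = 3)
    b <- synth_signal(kind, fs = 200, duration = 5, seed = 3)
    expect_identical(a$samples, b$samples)
  }
})

test_that("double sinusoid is Hanning-enveloped with peaks at both tones", {
  sig <- gen_double_sinusoid(fs = 1000, duration = 10, noise_sd = 0)
  expect_equal(sig$samples[1], 0)
  expect_equal(sig$samples[sig$n], 0)
  # dominant periodogram peaks at 10 and 50 Hz
  spec <- Mod(fft(sig$samples))^2
  freqs <- (seq_along(spec) - 1) * sig$fs / sig$n
  half <- freqs < sig$fs / 2
  expect_lt(abs(freqs[half][which.max(spec[half])] - 50), 0.5)
  low <- half & freqs > 5 & freqs < 15
  expect_lt(abs(freqs[low][which.max(spec[low])] - 10), 0.5)
  # the two tones dominate: everything off the two peaks is far weaker
  offpeak <- half & abs(freqs - 10) > 2 & abs(freqs - 50) > 2
  expect_gt(max(spec[low]), 100 * max(spec[offpeak]))
  # different seeds differ only in the (enveloped) noise component
  s1 <- gen_double_sinusoid(fs = 500, duration = 4, noise_sd = 0.05, seed = 1)
  s2 <- gen_double_sinusoid(fs = 500, duration = 4, noise_sd = 0.05, seed = 2)
  h <- ispct:::hanning(s1$n)
  d <- (s1$samples - s2$samples)[h > 0.5] / h[h > 0.5]
  expect_lt(abs(sd(d) - sqrt(2) * 0.05), 0.01) # difference is pure noise
})

test_that("double pulse occupies exactly its stated intervals and carriers", {
  sig <- gen_double_pulse(fs = 1000, duration = 50, noise_sd = 0)
  t <- seq_len(sig$n) / sig$fs
  outside <- t < 10 | (t > 10.5 & t < 25) | t > 26.5
  expect_true(all(sig$samples[outside] == 0))
  in1 <- t >= 10 & t <= 10.5
  expect_gt(max(abs(sig$samples[in1])), 0.5)
  # carrier frequency via zero-crossing count: 30 Hz over 0.5 s ~ 30 crossings
  x1 <- sig$samples[in1]
  crossings <- sum(diff(sign(x1[x1 != 0])) != 0)
  expect_lte(abs(crossings - 30), 2)
  in2 <- t >= 25 & t <= 26.5
  x2 <- sig$samples[in2]
  expect_lte(abs(sum(diff(sign(x2[x2 != 0])) != 0) - 15), 2)
})

test_that("chirps sweep quadratically between their stated frequencies", {
  sig <- gen_double_chirp(fs = 1000, duration = 50, noise_sd = 0)
  t <- seq_len(sig$n) / sig$fs
  outside <- t < 10 | (t > 10.5 & t < 25) | t > 26.5
  expect_true(all(sig$samples[outside] == 0))
  # instantaneous frequency of chirp 1 (20 -> 50 Hz in [10, 10.5] s);
  # estimate from the analytic phase away from the envelope edges
  k <- which(t >= 10 & t <= 10.5)
  fi <- inst_freq(sig$samples[k], sig$fs)
  tau <- (t[k][-1] - 10) / 0.5
  want <- 20 + (50 - 20) * tau^2
  mid <- tau > 0.15 & tau < 0.85
  expect_lt(max(abs(fi[mid] - want[mid])), 3)
  # monotone increase of the (smoothed) instantaneous frequency
  sm <- stats::filter(fi[mid], rep(1 / 25, 25))
  expect_true(all(diff(sm[!is.na(sm)]) > -0.05))
})

test_that("square wave follows the odd-harmonic expansion", {
  fs <- 1000; f <- 2
  one <- gen_square_wave(fs, 10, f, n_harmonics = 1, noise_sd = 0)
  t <- seq_len(one$n) / fs
  expect_equal(one$samples, 4 / pi * sin(2 * pi * f * t), tolerance = 1e-12)
  # amplitude ratios 1 : 1/3 : 1/5 at f, 3f, 5f
  three <- gen_square_wave(fs, 10, f, n_harmonics = 3, noise_sd = 0)
  spec <- Mod(fft(three$samples)) / three$n * 2
  bin <- function(fq) round(fq * three$n / fs) + 1
  amp <- spec[bin(c(f, 3 * f, 5 * f))]
  expect_equal(amp / amp[1], c(1, 1 / 3, 1 / 5), tolerance = 1e-6)
  # truncation error against the ideal square wave shrinks with more
  # harmonics (RMS: the pointwise maximum saturates at the Gibbs overshoot)
  ideal <- sign(sin(2 * pi * f * t))
  dev <- sapply(c(1, 4, 16, 64), function(nh) {
    sqrt(mean((gen_square_wave(fs, 10, f, n_harmonics = nh, noise_sd = 0)$samples - ideal)^2))
  })
  expect_true(all(diff(dev) < 0))
  # harmonics beyond Nyquist are refused
  expect_error(gen_square_wave(fs = 100, duration = 5, f = 2, n_harmonics = 13),
               class = "ispct_alias")
})

test_that("exponential signal starts at ~1 and increases strictly", {
  sig <- gen_exponential(fs = 100, duration = 5, noise_sd = 0)
  expect_equal(sig$samples[1], exp(0.01)) # first sample at t = dt
  expect_lt(abs(sig$samples[1] - 1), 0.02)
  expect_true(all(diff(sig$samples) > 0))
})

test_that("white noise generator has the declared marginal and no memory", {
  sig <- gen_white_noise(fs = 1000, duration = 20, kind = "uniform", seed = 5)
  x <- sig$samples
  expect_true(all(x >= 0 & x <= 1))
  expect_lt(abs(mean(x) - 0.5), 4 * sqrt(1 / 12) / sqrt(sig$n))
  r1 <- cor(x[-1], x[-sig$n])
  expect_lt(abs(r1), 4 / sqrt(sig$n))
  g <- gen_white_noise(fs = 1000, duration = 5, kind = "gaussian", seed = 5)
  expect_gt(diff(range(g$samples)), 4) # plainly not uniform on [0,1]
})

test_that("every generator except the exponential passes the preconditions", {
  for (kind in c("double_sinusoid", "double_pulse", "double_chirp",
                 "square_wave", "white_noise")) {
    sig <- synth_signal(kind, fs = 1000, duration = 50, seed = 2)
    rep <- check_preconditions(sig)
    expect_true(rep$ok, info = kind)
  }
  expect_false(check_preconditions(gen_exponential(seed = 2))$ok)
})
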