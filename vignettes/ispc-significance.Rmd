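---
title: "Testing the significance of inter-scale wavelet power correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the significance of inter-scale wavelet power correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ispct)
```

## The question and the model

Given one non-stationary, uniformly sampled time series, which frequency
bands carry power that genuinely co-varies over time? The naive approach —
decompose the signal time-frequency-wise, correlate the power of band *a*
with the power of band *b* over time, and keep the large correlations — is
badly biased for a continuous wavelet transform (CWT), for three reasons:

1. **Frequency-domain oversampling.** Adjacent CWT scales overlap in
   frequency, so their power series are correlated no matter what the input
   is. This is a property of the decomposition, not of the signal.
2. **Time-domain oversampling.** A wavelet spanning many samples makes
   consecutive same-scale power values strongly autocorrelated, and the
   sampling variance of a correlation between two autocorrelated series is
   far larger than the i.i.d. formula suggests.
3. **Signal non-stationarity.** Slow power modulation in the signal itself
   adds further intra-scale autocorrelation beyond what the transform
   induces.

The package tests each element $r_{a,b}$ of the inter-scale power
correlation matrix (ISPCM) against a per-pair normal null that accounts for
all three effects:

$$\chi_{a,b} \sim N\!\left(\bar\rho_{a,b} + \bar\phi_{a,b},\,
  \mathrm{Var}(\phi_{a,b})\right),$$

where $\bar\rho$ is the mean ISPCM of white-noise input (a Monte Carlo
estimate of the oversampling bias, `white_noise_mean_ispcm()`), and the
$\phi$ moments come from phase-randomized surrogates of the data,
re-correlated `H` times (`phase_rand_null()`).
Standardized statistics $T_{a,b} = (r_{a,b} - \bar\chi_{a,b}) /
\mathrm{SD}(\chi_{a,b})$ are thresholded with the Cai–Liu
false-discovery-rate procedure for dependent correlation statistics
(`cai_liu_threshold()`): the data-driven threshold $\hat t$ is the smallest
$t \le d_u = \sqrt{4\log u - 2\log\log u}$ with
$G(t)\,\binom{u}{2} / \max(R(t),1) \le \alpha$, $G(t) = 2 - 2\Phi(t)$,
falling back to $\hat t = 2\sqrt{\log u}$ when no $t$ qualifies (natural
logarithms throughout). Since $G$ is continuous and monotone and $R$ changes
only at observed $|T|$ values, evaluating the criterion at those candidates
gives the exact infimum's rejection set with no numerical tolerance.

Adding $\bar\rho$ to the null mean is equivalent to subtracting the
transform's intrinsic bias from the measured correlation. It is a
deliberately conservative correction: near the diagonal, where scales
overlap heavily, $\bar\rho$ approaches 1 and even a perfect measured
correlation may stay non-significant. Far from the diagonal $\bar\rho$
vanishes and the correction has no effect.

## The pipeline and its tunable parameters

`run_ispc_test()` executes: clip → (optional length standardization) → CWT →
power spectrum → COI filtering → ISPCM → two-element null → $T$ → Cai–Liu.

**Clipping** (`clip_to_cycle()`). Phase randomization treats each power
series as circular, so the signal is truncated at the last sample that
returns to within 1% of the first sample, then zero-meaned. Two readings of
"within 1%" are supported: relative to $|x_1|$ (default) and relative to the
peak-to-peak range. We default to the first because it is the only reading
under which strongly monotonous signals fail as they must: 1% of the range
of $e^t$ over 50 s is astronomically large, and an exponential would clip
"successfully" at 91% of its length, which is exactly the class of signal
the method cannot treat. With the default, the exponential retains under 1%
of its samples and is rejected (condition `ispct_no_clip_point`) whenever
the clipped remnant would be shorter than `min_frac` (default 0.5) of the
input. A numerical floor of $10^{-15}\times$ range lets signals that start
at exact zero (e.g. anything Hanning-enveloped) match an exactly-zero tail.
The clip rule needs *some* late near-recurrence of $x_1$; for short signals
whose first value is atypical, this can fail even for well-behaved inputs —
that is a property of the method, reported rather than papered over.

**Wavelet** (`morse_params()`). Analytic generalized Morse wavelet,
$\hat\psi(\omega) \propto \omega^\beta e^{-\omega^\gamma}$, with
$\gamma = 3$ ("Airy" family) and $\beta = 20$ — the defaults of the common
MATLAB implementation, whose printed order corresponds to $\beta$ here
(time–bandwidth product $P^2 = \beta\gamma = 60$). Scale grid: 10 voices per
octave, from the Nyquist frequency down to the frequency whose edge-effect
half-width reaches mid-signal (both overridable via `freq_limits`).
Per-scale amplitude normalization is immaterial: Pearson correlation is
invariant to positive rescaling of either power series, so every quantity
this package reports is normalization-free.

**COI** (`in_coi_mask()`, `coi_trim()`). The edge-affected zone of each
scale is taken as the one-sided e-folding time of the wavelet's time-domain
envelope (computed numerically once per $(\gamma,\beta)$ and scaled). Scales
with under 90% of samples inside the cone of influence are dropped; the
surviving scales are restricted to the widest common window in which every
cell is edge-free. Because COI spans are nested across scales, this common
window equals the in-COI span of the widest retained scale, so "widest
common window" and "intersection of spans" coincide; one shared window makes
every pairwise correlation use the same samples and is orders of magnitude
cheaper than per-pair windows.

**Monte Carlo sizes.** `L` (white-noise draws for $\bar\rho$) mainly sets
the bias of the oversampling estimate; `H` (phase-randomization draws) sets
the precision of the null mean and variance. Defaults are `L = 1000`,
`H = 250` for real analyses; the synthetic validation suite uses `L = 250`,
`H = 150` at $\alpha = 0.001$, 50 s at 1 kHz. All Monte Carlo stages draw
through per-iteration seeds derived from one root seed (`derive_seed()`), so
results are bit-reproducible and independent of execution order.

**Surrogate method.** The Fourier-transform (FT) surrogate preserves the
amplitude spectrum (hence autocovariance) and the mean and variance exactly,
but not the sample histogram — surrogates of a strictly positive power
series routinely go negative. The IAAFT variant preserves the histogram
exactly and the spectrum approximately, but its null correlations are often
non-normal, which conflicts with the normality the multiple-testing step
assumes; FT is therefore the default and IAAFT an option.
`normality_diagnostics()` checks the per-pair nulls (Shapiro–Wilk with
Benjamini–Hochberg control across pairs) if you want evidence for your own
data.

**Surrogate scope.** This was a genuinely open design point, and the package
exposes both answers.

* `surrogate_scope = "scale"` (default) randomizes each scale's *power
  series* independently. The surrogate pair keeps each band's power
  autocovariance — including autocorrelation contributed by the signal's
  own non-stationarity — and destroys all cross-band alignment, so
  $\bar\phi \approx 0$ everywhere and adding $\bar\rho$ to the null mean
  introduces no double counting. This is the appropriate null for
  broadband stochastic recordings, where each band's power has hundreds of
  effective degrees of freedom. Its blind spot is deterministic shared
  envelopes: a 50 s Hanning-enveloped tone's power series is essentially
  three Fourier bins, surrogate correlations then have $\mathrm{SD}(\phi)
  \approx 0.5$, and no correlation, however perfect, can reach
  significance.
* `surrogate_scope = "signal"` randomizes the phases of the *whole clipped
  signal* and re-decomposes each surrogate through the identical CWT/COI
  path. The null hypothesis becomes "a stationary signal with the data's
  amplitude spectrum": deterministic envelopes are destroyed in the
  surrogate, so shared slow power modulation — exactly what the synthetic
  validation signals contain — becomes detectable. Because both surrogate
  bands are filtered from one surrogate signal, $\bar\phi$ retains the
  band-overlap correlation near the diagonal; the combined null mean
  $\bar\rho + \bar\phi$ then deliberately over-corrects there, which is
  the conservative behaviour the near-diagonal region is supposed to have.

**Rejection tail.** The threshold search supports the symmetric rule
(reject $|T| \ge \hat t$, default) and a one-sided rule (reject $T \ge
\hat t$ with $G(t) = 1 - \Phi(t)$). The one-sided rule operationalizes
"is the measured correlation *larger* than the null predicts" and is the
right companion to `scope = "signal"`: there the null mean over-corrects
near the diagonal by construction, and a two-sided rule would convert that
deliberate conservatism into spurious negative-$T$ rejections hugging the
diagonal. The validation suite therefore runs `scope = "signal"`,
`tail = "greater"`; the default configuration (`"scale"`, two-sided) keeps
the literal standardized statistic semantics for stochastic data.

## What the synthetic generators emulate

The generators (`gen_*`, all deterministic given a seed, defaults 50 s at
1 kHz) provide six validation signals: two Hanning-enveloped tones at
10 and 50 Hz; two Hanning pulses (30 Hz in 10–10.5 s, 5 Hz in 25–26.5 s);
two quadratic chirps (20→50 Hz and 1→5 Hz over the same intervals); a
truncated odd-harmonic square-wave expansion at 2 Hz ("low-amplitude"
Gaussian noise, sd 0.05 against unit carriers, everywhere); $e^t$ plus
noise; and uniform white noise on $[0,1]$. Signals use the $t = k/f_s$,
$k = 1..n$ time convention (first sample one interval after zero) — visible
only in the square wave, which then starts on its Gibbs plateau rather than
at an isolated zero, making the clip rule behave like every other plateau
sample. The outcomes the suite reproduces: 2 carrier-centred groupings
each for the pulse and the chirp, strong significance among the square
wave's harmonically related bands with a conservative near-diagonal
low-frequency hole, a clip error for the exponential, and an empty mask for
white noise. The double sinusoid behaves differently from the other
signals: its Hanning envelope spans the whole record, so every scale's
power genuinely co-varies with every other and the map is broadly
significant, while the tone-core pairs themselves are untestable (next
section).

These signals exercise sensitivity and specificity, but they are stationary
mixtures of deterministic components plus modest i.i.d. noise: passing them
says nothing about line-noise contamination, referencing artifacts, or
slowly drifting recording gain in real electrophysiology, all of which can
create genuine (but uninteresting) cross-frequency power correlation that
this test will faithfully flag as significant.

## Numerical choices

* **FFT lengths.** The CWT zero-pads to the next 5-smooth composite length
  at least 15% beyond the signal: R's mixed-radix FFT stays fast without the
  up-to-2x padding of a power of two, and the headroom keeps circular
  wrap-around several e-folding widths away from any in-COI coefficient of a
  retained scale. The analysis window (after COI trimming) is likewise
  shaved — by at most a fraction of a percent — to the nearest 5-smooth
  length, so the per-iteration surrogate FFTs never hit a slow prime length
  (`fft_friendly_window`, on by default).
* **Null noise marginal.** Near Nyquist a wavelet averages so few samples
  that the input's marginal distribution survives into the power
  correlations; a null built from noise with a different marginal is
  miscalibrated exactly there. `noise_kind` selects gaussian (default) or
  uniform white noise for $\bar\rho$; `run_validation_suite()` matches it to
  each signal's noise (uniform for the uniform white-noise signal). For real
  data the gaussian default is appropriate. The white-noise draws are not
  clipped — clipping is signal preprocessing, and the draws are generated
  directly at the clipped length.
* **Degenerate pairs.** Zero-variance scales cannot be correlated and
  zero-variance nulls cannot standardize; both are reported as *untested*,
  never as non-significant. Inside `run_ispc_test()` a degenerate scale
  aborts the run rather than silently desynchronizing the data and null
  grids.
* **Variance estimator.** $\mathrm{Var}(\phi)$ is the unbiased sample
  variance over `H` iterations. With `H = 150` its own relative error is
  about 12%, which slightly fattens the tails of $T$; the conservative
  $\bar\rho$ correction and the strict validation $\alpha$ absorb this in
  practice.
* **Ties and the infimum.** The Cai–Liu criterion is evaluated at
  $\{0\} \cup \text{sorted } |T| \cup \{d_u\}$; between candidates $R(t)$ is
  constant, so the returned threshold may sit above the continuous infimum
  but selects the identical rejection set.

## Problem sizes used in the tests

Unit tests run on 8–30 s signals at 125–500 Hz (a few thousand samples,
30–70 scales), where every Monte Carlo property is checkable in seconds. The
acceptance tests and `scripts/acceptance.R` run the validation suite at its
native settings (50 s, 1 kHz, ~95 retained scales spanning 0.74–500 Hz,
`L = 250`, `H = 150`); each full run takes a few minutes on one CPU, almost
entirely FFTs and standardized matrix products.

## Known limitations

* **Whole-record envelopes are undetectable at their own scales.** A power
  series modulated by a single record-length envelope has only a few
  effective Fourier degrees of freedom; any surrogate that preserves its
  amplitude spectrum (FT or IAAFT, per scale or whole-signal) produces null
  correlations with a spread near 0.5 for such pairs, so even a measured
  correlation of 0.999 between two enveloped tones cannot reach
  significance. Transient envelopes (pulses, chirps — anything much shorter
  than the record) have many envelope degrees of freedom and are detected
  reliably. This is intrinsic to surrogate-based nulls, not an
  implementation parameter.
* The test is one data point per (pair, recording): it says a correlation is
  incompatible with the null, not how large or stable it is.
* Near-diagonal low-frequency pairs are tested very conservatively (large
  $\bar\rho$, large $\mathrm{Var}(\phi)$); true coupling there will often be
  missed, visibly so in the square-wave validation.
* Lagged and nonlinear dependence are out of scope: the statistic is the
  zero-lag Pearson correlation of power.
* The clip rule assumes the signal revisits its starting level late in the
  recording; strongly monotonous signals are rejected by design, and
  windowing alternatives are not implemented.
* Surrogate normality is assumed (and checkable), not guaranteed; with the
  IAAFT option the downstream FDR control may be invalid.
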