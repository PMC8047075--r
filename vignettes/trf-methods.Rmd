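---
title: "Methods: word-level TRF estimation for two-talker EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: word-level TRF estimation for two-talker EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(speechTRF)
```

This vignette documents the statistical model, its assumptions, the
default parameters, the design of the synthetic-data generator, and the
numerical choices made throughout `speechTRF`. Code chunks are shown but
not evaluated; the quantitative behavior of every component is exercised
by the test suite (`tests/testthat/`) and the end-to-end run
(`scripts/acceptance.R`).

## 1. The forward encoding model

The EEG at channel $c$ is modeled as a linear convolution of $F$
word-feature regressors $s_f(t)$ with feature- and channel-specific
kernels (TRFs) $h_{f,c}(\tau)$ plus noise:

$$
y_c(t) \;=\; \sum_{f=1}^{F} \sum_{\tau \in \mathcal{T}}
  h_{f,c}(\tau)\, s_f(t-\tau) \;+\; \varepsilon_c(t),
$$

with the lag set $\mathcal{T}$ spanning 0–780 ms by default. Each
regressor is an impulse train: zero except at the EEG sample nearest each
word onset (ties round down; two words on one sample sum), where it
carries the word's feature value. The four features are the word onset
(constant 1), semantic dissimilarity, lexical surprisal, and scaled
audibility; `rms_normalize()` scales each feature's nonzero amplitudes to
unit RMS so kernels are comparable across features.

**Assumptions.** Linearity and time invariance of the feature-to-EEG
mapping within a block; stationarity of the noise within blocks;
independence across blocks (designs are built per block, so no lagged
copies leak across block boundaries); and that word-level impulses are
an adequate parameterization of the response (no within-word dynamics
beyond the kernel itself).

## 2. Word-level features

- **Semantic dissimilarity** (`semantic_dissimilarity`):
  $d_w = 1 - \mathrm{corr}(v_w, \bar{v}_{\text{context}})$, where the
  context is the mean embedding of all preceding words in the same
  sentence; sentence-initial words use the previous sentence's mean. The
  first word of a recording has no context and receives the mean of the
  other words' values. Range $[0, 2]$.
- **Lexical surprisal** (`word_surprisal`): a word's probability is the
  product of its tokens' conditional probabilities, so
  $S(w) = -\log_{10} \prod_t p_t$ is additive over tokens and
  nonnegative.
- **Audibility** (`word_audibility`, `scale_audibility`): per-word
  target-to-masker RMS ratio in dB over the word interval,
  $20 \log_{10}(\mathrm{RMS_T}/\mathrm{RMS_M})$, clipped to $\pm 10$ dB
  and mapped linearly to $[0, 1]$. Infinite values from a silent masker
  or target clip to 1 or 0.

## 3. Preprocessing

`bandpass_1_8()` applies a 1–8 Hz Chebyshev type-II band-pass: at least
80 dB attenuation below 0.5 Hz and above 9 Hz, at most 1 dB pass-band
ripple. The filter is designed analytically — closed-form analog
zero-pole prototype, frequency transform, bilinear mapping — and realized
as a cascade of second-order sections (high-pass then low-pass), each
applied forward and backward (`filtfilt`) per channel per block, so the
net filter is zero-phase and latencies are untouched. A single
transfer-function (b, a) realization of the equivalent order-30 band-pass
would be numerically unusable at these normalized frequencies; the SOS
cascade keeps every section well conditioned. `zscore_eeg()` standardizes
each channel; `roi_average()` averages electrode sets (frontal/parietal
defaults in `default_rois()`); `half_gain_profile()` implements the
half-gain hearing-loss compensation rule, $A(f) = 0.5\,(T(f) - 20)$ for
thresholds above 20 dB HL and 0 otherwise.

## 4. Estimation

`ridge_fit()` minimizes $\|y - Xb\|^2 + \lambda \|b_p\|^2$, penalizing
all coefficients except the intercept, via Cholesky on the regularized
normal equations. `crossval_trf()` runs nested block-wise
cross-validation: the blocks split into `n_folds` outer folds (default
11); within each fold's training blocks, an inner leave-one-block-out
search scores every $\lambda \in \{10^{-2}, \dots, 10^{6}\}$ (one per
decade) by mean held-out Pearson $r$ across blocks and channels, ties
resolved toward the smallest $\lambda$. The model is refit on all
training blocks at the selected $\lambda$ and evaluated on the held-out
test blocks — per test block then averaged (default), or on the
concatenated test set. Per-block cross-products $X^\top X$, $X^\top y$
are precomputed once, so the inner search only re-solves small systems.

```{r fit}
fit <- crossval_trf(recording, regressors, n_folds = 11,
                    lambda_grid = 10^seq(-2, 6), lag_ms = c(0, 780))
```

**Feature contributions.** `feature_contribution()` permutes one
feature's regressor amplitudes across a fold's test blocks (timing and
the other features intact), re-evaluates the *already fitted* TRFs, and
reports $\Delta r = r_{\text{full}} - \overline{r_{\text{null}}}$
averaged over folds. No refitting occurs, so $\Delta r$ isolates the
feature's unique predictive value at test time. The onset feature's
amplitudes are constant after normalization, so its permutation is the
identity and $\Delta r \equiv 0$ exactly — a built-in negative control.
Because correlated features share predictive variance (the generator
couples dissimilarity and surprisal at $r = 0.22$), single-feature
$\Delta r$ values are not additive.

## 5. Group statistics

`pointwise_ttest()` runs vectorized paired or Welch t-tests at every
(channel, lag) point; `fdr_bh()` applies Benjamini–Hochberg step-up
correction; `window_mean()` averages TRFs over 300–500 ms (the
N400 range). `cluster_permutation()` controls family-wise error
nonparametrically: points with uncorrected two-tailed $p$ below
`cluster_alpha` form spatio-temporally contiguous clusters (adjacent lags
on a channel, adjacent channels at a lag), each scored by its summed
t-values; observed cluster statistics are compared against the
permutation null of the maximum absolute cluster sum (sign flips when
paired, group-label shuffles otherwise), with the add-one Monte-Carlo
p-value $(1 + \#\{\text{null} \ge |s|\})/(1 + n_{\text{perm}})$. When
the number of distinct relabelings is at most `n_perm`, the null is
enumerated exhaustively.

## 6. The synthetic-data generator

The generator is built to make the estimation code falsifiable, not to
imitate real EEG in detail:

- **Word streams**: log-normal word durations (median 0.3 s,
  `sdlog` 0.4) and exponential inter-word gaps capped at 0.5 s emulate
  forced-aligned narration whose silences were truncated; sentence runs
  of 5–15 words give the dissimilarity feature a realistic context
  structure.
- **Feature values**: a Gaussian copula couples dissimilarity
  (beta(5,5) scaled to $[0,2]$) and surprisal (log-normal, right-skewed)
  at a configurable Pearson correlation (default 0.22) while audibility
  stays independent and uniform. The latent correlation is calibrated by
  root-finding on a fixed common-random-number draw, so the *observed*
  correlation of the transformed marginals hits the target.
- **Kernels**: gamma-shaped biphasic bumps — early positive (~100 ms)
  for onset and audibility, late negative (~400 ms) for dissimilarity
  and surprisal — with smooth Gaussian channel topographies, echoing the
  early obligatory response and N400-range effects the estimator is
  meant to detect.
- **Noise**: 1/f ("pink") spectrally shaped Gaussian noise by default,
  matching the gross EEG spectrum; white noise optionally.
- **Stand-ins for external resources**: clustered random embeddings,
  exponential per-token probabilities, and amplitude-modulated noise
  audio let the full feature-derivation path run without any pre-trained
  model or recorded speech.

All generators consume explicit integer seeds and are bit-reproducible.

## 7. Numerical choices

- Ridge solves use Cholesky on $X^\top X + \lambda D$ (positive definite
  for $\lambda > 0$); the test suite checks agreement with direct solves
  to $10^{-8}$ on random systems.
- The filter is designed from an analytic zero-pole-gain prototype and
  kept in second-order sections throughout; section gains are spread
  evenly to avoid overflow/underflow between sections.
- Lag grids are derived with epsilon-guarded `ceiling`/`floor` so a
  780 ms window at 64 Hz yields the same grid whether built from
  milliseconds or samples.
- Tables serialized as TSV use `%.17g` formatting so doubles round-trip
  bit-exactly; EEG is stored as little-endian float32 with a JSON
  sidecar.
- Cluster-permutation t-maps are computed with vectorized column
  operations over a subjects × points matrix, which keeps a
  500-permutation test on a 8 × 50 grid under a second.

## 8. Limitations

- The model is linear and word-impulse based: envelope tracking,
  phoneme-level structure, and nonlinear (e.g. attention-gain) dynamics
  are outside its scope.
- Feature contributions are defined against an amplitude-permutation
  null; they quantify unique *test-time* predictive value, not causal
  contribution, and are not additive across correlated features.
- The synthetic generator's realism claims are structural (timing
  statistics, marginals, correlation, kernel shapes, 1/f noise), not
  physiological; absolute effect sizes in real data will differ.
- Welch t-maps reuse the pooled-df threshold for cluster formation, as
  is conventional; cluster inference is over the maxsum statistic and
  does not license point-wise localization claims inside a significant
  cluster.
- The audio path assumes both talkers share one clock and a common
  sample rate; no resampling is implemented (inputs must arrive on the
  EEG-compatible grid, or be resampled upstream).
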