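# speechTRF

Forward encoding models of EEG responses to two-talker speech, built
around word-level linguistic and acoustic features.

## Scientific problem

When a listener attends to one talker while a second talker competes, the
EEG tracks the attended speech stream. Beyond acoustic tracking, cortical
responses carry signatures of *linguistic* processing: a word's semantic
fit with its context (indexed by N400-range activity around 300–500 ms
after word onset), its lexical predictability, and how audible it was
against the competing talker. This package estimates those signatures
with **temporal response functions (TRFs)**: linear kernels mapping
word-level feature time series to the continuous EEG.

Each word contributes an impulse at its onset, scaled by four features:

- **onset** — constant 1 per word (obligatory response);
- **semantic dissimilarity** — `1 − corr(v_w, mean of preceding
  same-sentence word vectors)`, with sentence-initial words compared to
  the previous sentence's mean vector (range \[0, 2\]);
- **lexical surprisal** — `S(w) = −log10 ∏_t p(token_t | context)`,
  summed over the word's tokens;
- **audibility** — `Aud = 20·log10(RMS_target / RMS_masker)` over the word
  interval, clipped to ±10 dB and rescaled to \[0, 1\] via
  `(Aud + 10)/20`.

Nonzero amplitudes of each regressor are normalized to unit RMS so the
fitted kernels are on a common scale.

## Model

With lagged design matrix `X` (lags 0–780 ms, all features, plus an
unpenalized intercept) and EEG `y` per channel, coefficients solve the
ridge problem

```
b̂ = argmin_b ||y − X b||² + λ ||b_p||²
```

inside a nested block-wise cross-validation: 11 outer folds (e.g. 40
train / 4 test blocks of 44), λ chosen per fold by inner
leave-one-block-out search over `10^-2 … 10^6` (one per decade; best mean
held-out Pearson r, ties to the smallest λ). Goodness of fit is the
Pearson correlation `r` between predicted and recorded EEG on held-out
blocks. A feature's unique **contribution** is
`Δr = r_full − mean(r_null)` where the null permutes that feature's
regressor amplitudes (timing kept) and reuses the fitted TRFs. Group
inference uses pointwise t-tests with Benjamini–Hochberg FDR correction,
300–500 ms window means, and spatio-temporal cluster-based permutation
tests (maxsum statistic).

A synthetic-data module generates the whole dataset — word streams,
correlated feature values (Gaussian copula, target
dissimilarity–surprisal r = 0.22), toy embeddings, token probabilities,
two-speaker audio, and EEG convolved from known ground-truth kernels —
so every estimation step is testable against known truth.

## Worked example

A small simulated dataset (6 blocks × 30 s at 32 Hz, 4 channels), fitted
and decomposed:

```r
library(speechTRF)
cfg <- sim_config(n_blocks = 6, block_duration_s = 30, sample_rate_hz = 32,
                  n_channels = 4, noise_sd = 0.5, seed = 1)
ev    <- gen_word_stream(cfg)          # 377 word events
ft    <- gen_feature_values(ev, cfg)
truth <- default_kernel_set(cfg$sample_rate_hz, cfg$n_channels,
                            lag_range_ms = c(0, 500), noise_sd = cfg$noise_sd)
sim   <- simulate_eeg(ev, ft, truth, cfg)

fit <- crossval_trf(sim$recording, sim$regressors, n_folds = 3,
                    lag_ms = c(0, 500))
fit
#> <trf_cv> 4 features x 17 lags (0-500 ms) x 4 channels
#>   mean fit r = 0.7143; lambda per fold: 10 10 10

cor(as.vector(fit$coef["dissimilarity", , ]),
    as.vector(kernel_array(truth)["dissimilarity", , ]))
#> [1] 0.962                      # ground-truth kernel recovery

feature_contribution(fit, sim$regressors, sim$recording,
                     n_perm = 10, seed = 2)
#> <contribution_table> channel-mean delta_r:
#>         onset dissimilarity     surprisal    audibility
#>       0.00000       0.01981       0.05803       0.02604

round(window_mean(fit, 300, 500), 3)   # N400-range window means
#>                  CH1    CH2    CH3    CH4
#> onset         -0.175 -0.128 -0.049 -0.010
#> dissimilarity -0.254 -0.545 -0.327 -0.096
#> surprisal     -0.105 -0.402 -0.588 -0.316
#> audibility    -0.023  0.008 -0.061 -0.125
```

The onset contribution is zero by construction (its amplitudes are
constant, so permuting them is the identity); dissimilarity and surprisal
show the late negative (N400-like) window means their generating kernels
encode.

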