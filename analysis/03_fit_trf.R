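#!/usr/bin/env Rscript
# Stage 3: fit the cross-validated TRF model.
#
# Reads the simulated EEG and word-feature regressors, runs 11-fold
# nested cross-validation (inner leave-one-block-out ridge-parameter
# search), and reports held-out fit and ground-truth kernel recovery.

suppressPackageStartupMessages(library(speechTRF))

rec <- read_eeg_raw("results/eeg")
reg <- read_regressors("results/regressors")
gt <- readRDS("results/truth.rds")

fit <- crossval_trf(rec, reg, n_folds = 11)
saveRDS(fit, "results/fit.rds")

fit_tab <- data.frame(channel = rec$channel_labels, fit_r = fit$fit_r)
write.table(format(fit_tab, digits = 4), "results/trf_fit.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

true_arr <- kernel_array(gt$truth)
rec_tab <- data.frame(
  feature = fit$features,
  recovery_r = sapply(fit$features, function(f) {
    cor(as.vector(fit$coef[f, , ]), as.vector(true_arr[f, , ]))
  }))
write.table(format(rec_tab, digits = 4), "results/kernel_recovery.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

print(fit)
cat("kernel recovery:\n")
print(rec_tab, row.names = FALSE)
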