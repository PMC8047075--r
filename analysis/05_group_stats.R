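#!/usr/bin/env Rscript
# Stage 5: group-level statistics over cross-validation folds.
#
# Treats the 11 fold-wise TRF estimates as replicates: (a) N400-window
# (300-500 ms) mean amplitudes per feature, tested against zero pointwise
# with BH-FDR correction across features; (b) a paired spatio-temporal
# cluster permutation test of the dissimilarity TRF against zero.

suppressPackageStartupMessages(library(speechTRF))

fit <- readRDS("results/fit.rds")
nf <- length(fit$features)
nl <- length(fit$lags)
nc <- length(fit$channel_labels)
nfold <- length(fit$folds)

# fold-wise coefficient arrays: fold x feature x lag x channel
fold_coef <- array(NA_real_, c(nfold, nf, nl, nc))
for (k in seq_len(nfold)) {
  beta <- fit$folds[[k]]$beta[-1, , drop = FALSE]
  fold_coef[k, , , ] <- aperm(array(beta, c(nl, nf, nc)), c(2, 1, 3))
}

# (a) channel-averaged N400-window means per fold and feature
win <- sapply(seq_len(nf), function(f) {
  sapply(seq_len(nfold), function(k) {
    mean(window_mean(fold_coef[k, , , , drop = TRUE], 300, 500,
                     lag_ms = fit$lag_ms)[f, ])
  })
})
colnames(win) <- fit$features
tt <- pointwise_ttest(win, matrix(0, nfold, nf), paired = TRUE)
bh <- fdr_bh(tt$p, 0.05)
tab <- data.frame(feature = fit$features,
                  window_mean = colMeans(win),
                  t = tt$t, df = tt$df, p = tt$p,
                  p_fdr = bh$p_adjusted, significant = bh$reject)
write.table(format(tab, digits = 4), "results/group_stats.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("N400-window (300-500 ms) fold-level tests:\n")
print(tab, row.names = FALSE)

# (b) cluster permutation: dissimilarity TRF vs zero across folds
di <- which(fit$features == "dissimilarity")
a <- aperm(fold_coef[, di, , , drop = TRUE], c(1, 3, 2))  # fold x ch x lag
ct <- cluster_permutation(a, array(0, dim(a)), channel_adjacency(nc),
                          n_perm = 1000, paired = TRUE, seed = 11L)
print(ct)
ctab <- data.frame(cluster = seq_along(ct$clusters),
                   sign = ct$sign, n_points = sapply(ct$clusters, nrow),
                   maxsum = ct$statistic, p = ct$p_value)
write.table(format(ctab, digits = 4), "results/clusters.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
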