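#' Permute a regressor's impulse amplitudes, keeping their timing
#'
#' Draws a uniformly random permutation of the nonzero amplitudes and
#' reassigns them to the original nonzero sample positions; zeros are
#' untouched. This destroys the association between word identity and
#' feature value while preserving the impulse timing and the amplitude
#' distribution.
#'
#' @param regressor numeric vector (one feature's sampled regressor) with
#'   at least 2 nonzero entries.
#' @param seed integer seed; the permutation is deterministic given it.
#' @return The permuted regressor vector.
#' @export
permute_feature <- function(regressor, seed) {
  nz <- which(regressor != 0)
  if (length(nz) < 2) stop("nothing to permute: fewer than 2 nonzero entries")
  set.seed(seed)
  out <- regressor
  out[nz] <- regressor[nz][sample.int(length(nz))]
  out
}

#' Permutation-null feature contributions to model fit
#'
#' Estimates each feature's unique contribution to the cross-validated
#' model fit. For every outer fold, the full-model held-out fit r is
#' compared against a null model in which the target feature's regressor
#' amplitudes are permuted (timing preserved, other features intact)
#' across the fold's test blocks jointly; predictions reuse the SAME
#' fitted TRFs -- no refitting. The permutation is repeated `n_perm`
#' times (fresh permutations per fold) and
#' `delta_r = r_full - mean(r_null)`, averaged over folds. The word-onset
#' feature has constant amplitudes after RMS normalization, so its
#' delta_r is zero by construction.
#'
#' @param fit a `trf_cv` from [crossval_trf()].
#' @param regressors the [regressor_set()] the model was fit with.
#' @param recording the [eeg_recording()] the model was fit on.
#' @param features features to evaluate (default: all in the model).
#' @param n_perm permutations per feature and fold (default 10).
#' @param seed master seed; per-(feature, fold, permutation) streams are
#'   derived from it.
#' @return A list of class `contribution_table`: `delta_r` (feature x
#'   channel matrix), `null_r` (feature x fold x permutation array of
#'   channel-mean null fits), `n_perm`, `features`.
#' @export
feature_contribution <- function(fit, regressors, recording,
                                 features = fit$features, n_perm = 10,
                                 seed = 1L) {
  if (!all(features %in% fit$features)) {
    stop("unknown target feature(s): ",
         paste(setdiff(features, fit$features), collapse = ", "))
  }
  lags <- fit$lags
  nc <- nrow(recording$data)
  nfold <- length(fit$folds)
  delta <- matrix(0, length(features), nc,
                  dimnames = list(features, recording$channel_labels))
  null_mean <- array(NA_real_, c(length(features), nfold, n_perm),
                     dimnames = list(features, NULL, NULL))
  vals <- regressors$values[, fit$features, drop = FALSE]
  for (k in seq_len(nfold)) {
    fold <- fit$folds[[k]]
    test <- fold$test_blocks
    rows <- unlist(lapply(test, function(b) {
      seq.int(regressors$block_bounds[b, 1], regressors$block_bounds[b, 2])
    }))
    blk_len <- regressors$block_bounds[test, 2] -
      regressors$block_bounds[test, 1] + 1L
    Y <- lapply(test, function(b) t(recording$data[, block_idx(recording, b),
                                                   drop = FALSE]))
    r_full <- fold$r_fold
    for (fi in seq_along(features)) {
      f <- features[fi]
      drop_sum <- numeric(nc)
      for (p in seq_len(n_perm)) {
        pseed <- (seed + 7919L * fi + 104729L * k + p) %% .Machine$integer.max
        v <- vals[rows, , drop = FALSE]
        pf <- permute_feature(v[, f], pseed)
        if (identical(pf, v[, f])) {
          # constant-amplitude feature (e.g. word onsets): the permutation
          # is the identity, so the null fit IS the full fit -- exactly
          null_mean[fi, k, p] <- mean(r_full)
          next
        }
        v[, f] <- pf
        # rebuild per-block designs with the permuted feature
        off <- c(0L, cumsum(blk_len))
        r_blocks <- matrix(NA_real_, nc, length(test))
        for (bi in seq_along(test)) {
          seg <- (off[bi] + 1L):off[bi + 1L]
          X <- lagged_design(v[seg, , drop = FALSE], lags)
          r_blocks[, bi] <- col_pearson(X %*% fold$beta, Y[[bi]])
        }
        r_null <- if (fit$test_eval == "per_block") rowMeans(r_blocks) else {
          Xall <- do.call(rbind, lapply(seq_along(test), function(bi) {
            seg <- (off[bi] + 1L):off[bi + 1L]
            lagged_design(v[seg, , drop = FALSE], lags)
          }))
          col_pearson(Xall %*% fold$beta, do.call(rbind, Y))
        }
        drop_sum <- drop_sum + (r_full - r_null)
        null_mean[fi, k, p] <- mean(r_null)
      }
      delta[fi, ] <- delta[fi, ] + drop_sum / n_perm
    }
  }
  structure(list(delta_r = delta / nfold, null_r = null_mean,
                 n_perm = n_perm, features = features),
            class = "contribution_table")
}

#' @export
print.contribution_table <- function(x, ...) {
  cat("<contribution_table> channel-mean delta_r:\n")
  print(round(rowMeans(x$delta_r), 5))
  invisible(x)
}
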