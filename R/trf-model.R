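#' Lagged (time-delayed) design matrix
#'
#' Builds the design matrix for TRF estimation by stacking time-lagged
#' copies of each feature regressor: column order is feature-major,
#' lag-minor, with an optional leading intercept column. Samples shifted
#' in from before the segment start are zero-padded, so a design built per
#' block never leaks information across block boundaries.
#'
#' @param x numeric matrix, samples x features (a single block or
#'   contiguous segment).
#' @param lags integer vector of nonnegative lags in samples.
#' @param intercept prepend an all-ones column (default TRUE).
#' @return Matrix with `attr(, "penalty")`, a logical vector marking which
#'   columns the ridge penalty applies to (the intercept is unpenalized).
#' @export
lagged_design <- function(x, lags, intercept = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  nf <- ncol(x)
  nl <- length(lags)
  out <- matrix(0, n, nf * nl + intercept)
  if (intercept) out[, 1] <- 1
  cn <- character(ncol(out))
  if (intercept) cn[1] <- "(Intercept)"
  fn <- colnames(x)
  if (is.null(fn)) fn <- paste0("feature", seq_len(nf))
  k <- intercept
  for (f in seq_len(nf)) {
    for (l in lags) {
      k <- k + 1
      if (l < n) out[(l + 1):n, k] <- x[seq_len(n - l), f]
      cn[k] <- sprintf("%s_lag%d", fn[f], l)
    }
  }
  colnames(out) <- cn
  attr(out, "penalty") <- c(rep(FALSE, as.integer(intercept)), rep(TRUE, nf * nl))
  out
}

#' Ridge regression solve
#'
#' Minimizes `||y - X b||^2 + lambda * ||b_p||^2` where `b_p` are the
#' penalized coefficients (all columns except any intercept, per the
#' design's `penalty` attribute). Solved by Cholesky on the regularized
#' normal equations; unique for `lambda > 0`.
#'
#' @param design matrix from [lagged_design()] (or any numeric matrix; a
#'   missing `penalty` attribute penalizes every column).
#' @param response numeric vector or samples x channels matrix.
#' @param lambda ridge parameter, >= 0.
#' @return Coefficient matrix, columns = response channels.
#' @export
ridge_fit <- function(design, response, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  response <- as.matrix(response)
  if (nrow(design) != nrow(response)) stop("design/response row mismatch")
  if (any(!is.finite(design)) || any(!is.finite(response))) {
    stop("non-finite values in design or response")
  }
  pen <- attr(design, "penalty")
  if (is.null(pen)) pen <- rep(TRUE, ncol(design))
  ridge_solve(crossprod(design), crossprod(design, response), lambda, pen)
}

ridge_solve <- function(XtX, Xty, lambda, penalty) {
  A <- XtX
  diag(A) <- diag(A) + lambda * penalty
  R <- chol(A)
  backsolve(R, backsolve(R, Xty, transpose = TRUE))
}

# columnwise Pearson correlation between two equal-shaped matrices
col_pearson <- function(a, b) {
  a <- sweep(as.matrix(a), 2, colMeans(a))
  b <- sweep(as.matrix(b), 2, colMeans(b))
  den <- sqrt(colSums(a^2) * colSums(b^2))
  out <- colSums(a * b) / den
  out[den == 0] <- NA_real_
  out
}

lag_samples <- function(lag_ms, fs) {
  seq.int(ceiling(lag_ms[1] * fs / 1000 - 1e-9),
          floor(lag_ms[2] * fs / 1000 + 1e-9))
}

# Precompute per-block design, response and cross-products.
prep_blocks <- function(recording, regressors, lags) {
  stopifnot(nrow(recording$block_bounds) == nrow(regressors$block_bounds))
  lapply(seq_len(n_blocks(recording)), function(b) {
    idx <- block_idx(recording, b)
    X <- lagged_design(regressors$values[idx, , drop = FALSE], lags)
    Y <- t(recording$data[, idx, drop = FALSE])
    list(X = X, Y = Y, XtX = crossprod(X), XtY = crossprod(X, Y),
         penalty = attr(X, "penalty"))
  })
}

select_lambda_prepped <- function(prep, train_blocks, lambda_grid) {
  lambda_grid <- sort(lambda_grid)
  pen <- prep[[train_blocks[1]]]$penalty
  score <- matrix(NA_real_, length(train_blocks), length(lambda_grid))
  for (h in seq_along(train_blocks)) {
    ho <- train_blocks[h]
    tr <- setdiff(train_blocks, ho)
    A <- Reduce(`+`, lapply(prep[tr], `[[`, "XtX"))
    bb <- Reduce(`+`, lapply(prep[tr], `[[`, "XtY"))
    for (g in seq_along(lambda_grid)) {
      beta <- ridge_solve(A, bb, lambda_grid[g], pen)
      r <- col_pearson(prep[[ho]]$X %*% beta, prep[[ho]]$Y)
      score[h, g] <- mean(r, na.rm = TRUE)
    }
  }
  mean_r <- colMeans(score, na.rm = TRUE)
  if (all(!is.finite(mean_r))) stop("lambda selection failed: all fits non-finite")
  list(lambda = lambda_grid[which.max(mean_r)],  # ties -> smallest (sorted grid)
       mean_r = stats::setNames(mean_r, lambda_grid))
}

#' Ridge-parameter selection by leave-one-block-out cross-validation
#'
#' For each candidate lambda, fits the model on all but one training block
#' and scores held-out prediction by Pearson r, averaged over held-out
#' blocks and channels; returns the candidate with the best average fit
#' (ties broken toward the smallest lambda).
#'
#' @param recording a preprocessed [eeg_recording()].
#' @param regressors a [regressor_set()] aligned to the recording.
#' @param blocks indices of the training blocks (>= 2).
#' @param lambda_grid candidate ridge parameters.
#' @param lag_ms fitting lag window in ms, default `c(0, 780)`.
#' @return List with `lambda` (the selection) and `mean_r` (per-candidate
#'   mean held-out fit).
#' @export
select_lambda <- function(recording, regressors, blocks,
                          lambda_grid = 10^seq(-2, 6), lag_ms = c(0, 780)) {
  if (length(blocks) < 2) stop("need at least 2 training blocks")
  if (length(lambda_grid) == 0) stop("empty lambda grid")
  lags <- lag_samples(lag_ms, recording$sample_rate_hz)
  prep <- prep_blocks(recording, regressors, lags)
  select_lambda_prepped(prep, blocks, lambda_grid)
}

#' Cross-validated TRF estimation
#'
#' Nested block-wise cross-validation for the multi-feature TRF model. The
#' blocks are partitioned into `n_folds` outer folds; in each fold the
#' remaining training blocks determine the ridge parameter by inner
#' leave-one-block-out search ([select_lambda()]), the model is refit on
#' all training blocks at the selected lambda, and goodness of fit is the
#' Pearson correlation between predicted and recorded EEG on each held-out
#' test block (averaged per block by default). The returned TRF and fit
#' are averages over all folds.
#'
#' @param recording a preprocessed [eeg_recording()] whose block count is
#'   divisible by `n_folds`.
#' @param regressors a [regressor_set()] aligned to the recording.
#' @param n_folds number of outer folds (default 11, giving a 40-train /
#'   4-test split of 44 blocks).
#' @param lambda_grid candidate ridge parameters (default one per decade,
#'   1e-2 to 1e6).
#' @param lag_ms fitting lag window in ms, default `c(0, 780)`.
#' @param test_eval `"per_block"` (Pearson r per test block, then
#'   averaged) or `"concatenated"` (one r over the concatenated test set).
#' @return An object of class `trf_cv`: `coef` (feature x lag x channel,
#'   fold-averaged), `intercept`, `lag_ms`, `lambda` (per fold), `fit_r`
#'   (per channel, fold-averaged), `folds` (per-fold detail), `features`,
#'   `sample_rate_hz`.
#' @export
crossval_trf <- function(recording, regressors, n_folds = 11,
                         lambda_grid = 10^seq(-2, 6), lag_ms = c(0, 780),
                         test_eval = c("per_block", "concatenated")) {
  test_eval <- match.arg(test_eval)
  nb <- n_blocks(recording)
  if (nb %% n_folds != 0) {
    stop(sprintf(
      "incompatible scheme: %d blocks cannot split into %d folds; nearest compatible fold counts: %s",
      nb, n_folds,
      paste(Filter(function(k) nb %% k == 0, seq_len(nb)), collapse = ", ")))
  }
  tpf <- nb %/% n_folds
  fs <- recording$sample_rate_hz
  lags <- lag_samples(lag_ms, fs)
  prep <- prep_blocks(recording, regressors, lags)
  pen <- prep[[1]]$penalty
  feats <- regressors$features
  nf <- length(feats); nl <- length(lags)
  nc <- nrow(recording$data)
  folds <- vector("list", n_folds)
  coef_sum <- array(0, c(nf, nl, nc))
  icpt_sum <- numeric(nc)
  r_sum <- numeric(nc)
  for (k in seq_len(n_folds)) {
    test <- ((k - 1) * tpf + 1):(k * tpf)
    train <- setdiff(seq_len(nb), test)
    sel <- if (length(train) >= 2) {
      select_lambda_prepped(prep, train, lambda_grid)
    } else list(lambda = lambda_grid[1], mean_r = NULL)
    A <- Reduce(`+`, lapply(prep[train], `[[`, "XtX"))
    bb <- Reduce(`+`, lapply(prep[train], `[[`, "XtY"))
    beta <- ridge_solve(A, bb, sel$lambda, pen)
    if (test_eval == "per_block") {
      r_blk <- sapply(test, function(b) {
        col_pearson(prep[[b]]$X %*% beta, prep[[b]]$Y)
      })
      r_fold <- rowMeans(as.matrix(r_blk))
    } else {
      P <- do.call(rbind, lapply(prep[test], function(p) p$X %*% beta))
      Y <- do.call(rbind, lapply(prep[test], `[[`, "Y"))
      r_blk <- r_fold <- col_pearson(P, Y)
    }
    coefs <- array(beta[-1, , drop = FALSE], c(nl, nf, nc))
    coefs <- aperm(coefs, c(2, 1, 3))
    coef_sum <- coef_sum + coefs
    icpt_sum <- icpt_sum + beta[1, ]
    r_sum <- r_sum + r_fold
    folds[[k]] <- list(test_blocks = test, lambda = sel$lambda,
                       beta = beta, r = as.matrix(r_blk), r_fold = r_fold)
  }
  coef_avg <- coef_sum / n_folds
  dimnames(coef_avg) <- list(feats, NULL, recording$channel_labels)
  structure(list(coef = coef_avg,
                 intercept = icpt_sum / n_folds,
                 lag_ms = lags / fs * 1000, lags = lags,
                 lambda = vapply(folds, `[[`, numeric(1), "lambda"),
                 fit_r = r_sum / n_folds,
                 folds = folds, features = feats,
                 channel_labels = recording$channel_labels,
                 sample_rate_hz = fs, test_eval = test_eval),
            class = "trf_cv")
}

#' @export
print.trf_cv <- function(x, ...) {
  cat(sprintf("<trf_cv> %d features x %d lags (%g-%g ms) x %d channels\n",
              dim(x$coef)[1], dim(x$coef)[2], min(x$lag_ms), max(x$lag_ms),
              dim(x$coef)[3]))
  cat(sprintf("  mean fit r = %.4f; lambda per fold: %s\n",
              mean(x$fit_r), paste(signif(x$lambda, 3), collapse = " ")))
  invisible(x)
}

#' Predict EEG from a fitted TRF model
#'
#' Convolves the (fold-averaged, or one fold's) TRFs with the supplied
#' feature regressors: prediction = lagged design x coefficients +
#' intercept, built block by block.
#'
#' @param object a `trf_cv` fit.
#' @param regressors a [regressor_set()] with the model's features.
#' @param fold fold index whose coefficients to use; `NULL` (default) uses
#'   the fold-averaged TRF.
#' @param ... unused.
#' @return Predicted data, channels x samples.
#' @export
predict.trf_cv <- function(object, regressors, fold = NULL, ...) {
  if (!all(object$features %in% regressors$features)) {
    stop("regressor features do not match the fitted model")
  }
  if (regressors$sample_rate_hz != object$sample_rate_hz) {
    stop("regressor rate must equal the model rate")
  }
  nf <- length(object$features)
  nl <- length(object$lags)
  beta <- if (is.null(fold)) {
    nc <- dim(object$coef)[3]
    rbind(object$intercept,
          matrix(aperm(object$coef, c(2, 1, 3)), nf * nl, nc))
  } else object$folds[[fold]]$beta
  vals <- regressors$values[, object$features, drop = FALSE]
  pred <- matrix(0, ncol(beta), nrow(vals))
  for (b in seq_len(nrow(regressors$block_bounds))) {
    idx <- seq.int(regressors$block_bounds[b, 1], regressors$block_bounds[b, 2])
    X <- lagged_design(vals[idx, , drop = FALSE], object$lags)
    pred[, idx] <- t(X %*% beta)
  }
  pred
}
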