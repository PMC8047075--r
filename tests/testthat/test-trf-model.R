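test_that("lagged designs are shifted unit columns with zero padding", {
  x <- matrix(0, 10, 1, dimnames = list(NULL, "f"))
  x[3, 1] <- 1
  X <- lagged_design(x, 0:2)
  expect_equal(ncol(X), 4)          # intercept + 3 lags
  expect_equal(X[, 1], rep(1, 10))
  expect_equal(which(X[, 2] != 0), 3)
  expect_equal(which(X[, 3] != 0), 4)
  expect_equal(which(X[, 4] != 0), 5)
  expect_equal(attr(X, "penalty"), c(FALSE, TRUE, TRUE, TRUE))
  Xz <- lagged_design(matrix(0, 5, 2), 0:1)
  expect_true(all(Xz[, -1] == 0))
})

test_that("per-block designs never leak regressor mass across blocks", {
  set.seed(4)
  v <- matrix(rnorm(40), 40, 1)
  whole <- lagged_design(v, 0:3, intercept = FALSE)
  stacked <- rbind(lagged_design(v[1:20, , drop = FALSE], 0:3, intercept = FALSE),
                   lagged_design(v[21:40, , drop = FALSE], 0:3, intercept = FALSE))
  # they differ exactly at the first 3 samples of block 2...
  expect_true(all(stacked[21:23, 2:4] == 0 | stacked[21:23, 2:4] == whole[21:23, 2:4]))
  expect_false(isTRUE(all.equal(whole, stacked)))
  # ...and agree everywhere else
  expect_equal(whole[-(21:23), ], stacked[-(21:23), ], ignore_attr = TRUE)
})

test_that("ridge at lambda=0 equals OLS and matches normal-equations oracle", {
  set.seed(5)
  X <- cbind(1, matrix(rnorm(10), 5, 2))
  attr(X, "penalty") <- c(FALSE, TRUE, TRUE)
  y <- rnorm(5)
  b0 <- ridge_fit(X, y, 0)
  expect_equal(as.numeric(b0), as.numeric(solve(crossprod(X), crossprod(X, y))),
               tolerance = 1e-10)
  # shrinkage limit: penalized coefficients vanish, intercept survives
  b_inf <- ridge_fit(X, y, 1e12)
  expect_lt(max(abs(b_inf[2:3])), 1e-6 * max(abs(b0[2:3])))
  expect_equal(b_inf[1], mean(y), tolerance = 1e-4)
  expect_error(ridge_fit(X, c(y, 1), 1), "mismatch")
  expect_error(ridge_fit(X, y, -1), "lambda")
})

test_that("ridge matches the regularized normal-equations oracle on random systems", {
  set.seed(6)
  worst <- 0
  for (i in 1:100) {
    n <- sample(10:30, 1); p <- sample(2:6, 1)
    X <- cbind(1, matrix(rnorm(n * p), n, p))
    attr(X, "penalty") <- c(FALSE, rep(TRUE, p))
    y <- rnorm(n)
    lambda <- 10^runif(1, -2, 3)
    D <- diag(c(0, rep(1, p)))
    oracle <- solve(crossprod(X) + lambda * D, crossprod(X, y))
    worst <- max(worst, max(abs(ridge_fit(X, y, lambda) - oracle)))
  }
  expect_lt(worst, 1e-8)
})

test_that("duplicating every training row preserves coefficients when lambda doubles", {
  # the penalty is on the raw sum-of-squares scale, so doubling the data
  # and the lambda together leaves the solution unchanged
  set.seed(7)
  X <- cbind(1, matrix(rnorm(30), 15, 2))
  attr(X, "penalty") <- c(FALSE, TRUE, TRUE)
  y <- rnorm(15)
  X2 <- rbind(X, X); attr(X2, "penalty") <- attr(X, "penalty")
  expect_equal(ridge_fit(X, y, 5), ridge_fit(X2, c(y, y), 10),
               tolerance = 1e-10)
})

test_that("lambda selection returns the grid optimum with smallest-lambda ties", {
  s <- small_sim()
  rec <- zscore_eeg(s$sim$recording)
  one <- select_lambda(rec, s$sim$regressors, blocks = 1:4,
                       lambda_grid = 42, lag_ms = c(0, 400))
  expect_equal(one$lambda, 42)
  sel <- select_lambda(rec, s$sim$regressors, blocks = 1:4,
                       lambda_grid = c(1e-2, 1, 1e2, 1e4), lag_ms = c(0, 400))
  expect_equal(sel$lambda, as.numeric(names(which.max(sel$mean_r))))
  expect_error(select_lambda(rec, s$sim$regressors, blocks = 1,
                             lambda_grid = 1), "at least 2")
})

test_that("more noise pushes the selected lambda up", {
  lam <- sapply(c(0.1, 3), function(ns) {
    cfg <- sim_config(n_blocks = 4, block_duration_s = 30, sample_rate_hz = 32,
                      n_channels = 2, noise_sd = ns, seed = 21)
    ev <- gen_word_stream(cfg); ft <- gen_feature_values(ev, cfg)
    truth <- default_kernel_set(32, 2, lag_range_ms = c(0, 400), noise_sd = ns)
    sim <- simulate_eeg(ev, ft, truth, cfg)
    select_lambda(zscore_eeg(sim$recording), sim$regressors, 1:4,
                  lambda_grid = 10^seq(-2, 6), lag_ms = c(0, 400))$lambda
  })
  expect_gt(lam[2], lam[1])
})

test_that("cross-validated TRFs recover the generating kernels", {
  s <- small_sim()
  rec <- zscore_eeg(s$sim$recording)
  fit <- crossval_trf(rec, s$sim$regressors, n_folds = 3, lag_ms = c(0, 500))
  ka <- kernel_array(s$truth)
  for (f in seq_along(fit$features)) {
    ch <- which.max(s$truth$topography[f, ])
    expect_gt(cor(fit$coef[f, , ch], ka[f, , ch]), 0.9)
  }
  expect_true(all(fit$fit_r > 0.3))
  expect_true(all(fit$fit_r >= -1 & fit$fit_r <= 1))
  expect_error(crossval_trf(rec, s$sim$regressors, n_folds = 4), "compatible")
})

test_that("pure-noise responses give fit r indistinguishable from zero", {
  s <- small_sim()
  set.seed(8)
  noise <- eeg_recording(matrix(rnorm(length(s$sim$recording$data)),
                                nrow(s$sim$recording$data)),
                         s$cfg$sample_rate_hz,
                         block_bounds = s$sim$recording$block_bounds)
  fit <- crossval_trf(noise, s$sim$regressors, n_folds = 3, lag_ms = c(0, 500))
  rs <- unlist(lapply(fit$folds, function(f) as.numeric(f$r)))
  se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs)), 2 * se + 0.02)
})

test_that("test-set shuffling leaves training TRFs untouched", {
  s <- small_sim()
  rec <- zscore_eeg(s$sim$recording)
  fit <- crossval_trf(rec, s$sim$regressors, n_folds = 3, lag_ms = c(0, 500))
  # corrupt the fold-1 test blocks (1, 2); refit and compare fold-1 betas
  rec2 <- rec
  set.seed(9)
  idx <- seq.int(rec$block_bounds[1, 1], rec$block_bounds[2, 2])
  rec2$data[, idx] <- rec2$data[, sample(idx)]
  fit2 <- crossval_trf(rec2, s$sim$regressors, n_folds = 3, lag_ms = c(0, 500))
  expect_equal(fit$folds[[1]]$beta, fit2$folds[[1]]$beta, tolerance = 1e-10)
})

test_that("predictions are the design-coefficient product plus intercept", {
  s <- small_sim()
  rec <- zscore_eeg(s$sim$recording)
  fit <- crossval_trf(rec, s$sim$regressors, n_folds = 3, lag_ms = c(0, 500))
  # zero regressors -> intercept-only prediction
  reg0 <- s$sim$regressors
  reg0$values[] <- 0
  p0 <- predict(fit, reg0, fold = 1)
  expect_equal(p0[, 1], fit$folds[[1]]$beta[1, ], ignore_attr = TRUE)
  expect_equal(max(apply(p0, 1, sd)), 0)
  # linearity: doubling one feature's regressor doubles its contribution
  regA <- s$sim$regressors
  regB <- s$sim$regressors
  regB$values[, "surprisal"] <- 2 * regB$values[, "surprisal"]
  pA <- predict(fit, regA, fold = 1)
  pB <- predict(fit, regB, fold = 1)
  regC <- s$sim$regressors
  regC$values[, setdiff(colnames(regC$values), "surprisal")] <- 0
  pS <- predict(fit, regC, fold = 1)
  icpt <- matrix(fit$folds[[1]]$beta[1, ], nrow(pA), ncol(pA), byrow = FALSE)
  expect_equal(pB - pA, pS - icpt, tolerance = 1e-8)
})

test_that("lambda=0 full-rank residuals are orthogonal to the design", {
  set.seed(10)
  x <- matrix(rnorm(200), 200, 1, dimnames = list(NULL, "f"))
  X <- lagged_design(x, 0:3)
  y <- rnorm(200)
  b <- ridge_fit(X, y, 0)
  res <- y - X %*% b
  expect_lt(max(abs(crossprod(X, res))), 1e-8)
})

test_that("fold averaging is invariant to block-label permutation of folds", {
  s <- small_sim()
  rec <- zscore_eeg(s$sim$recording)
  fit <- crossval_trf(rec, s$sim$regressors, n_folds = 3, lag_ms = c(0, 500))
  # reorder blocks so the folds appear in a different order; same partition
  perm <- c(5, 6, 1, 2, 3, 4)
  ord <- unlist(lapply(perm, function(b) {
    seq.int(rec$block_bounds[b, 1], rec$block_bounds[b, 2])
  }))
  rec_p <- eeg_recording(rec$data[, ord], rec$sample_rate_hz,
                         rec$channel_labels, rec$block_bounds)
  reg_p <- s$sim$regressors
  reg_p$values <- reg_p$values[ord, , drop = FALSE]
  fit_p <- crossval_trf(rec_p, reg_p, n_folds = 3, lag_ms = c(0, 500))
  expect_equal(fit$coef, fit_p$coef, tolerance = 1e-8)
  expect_equal(mean(fit$fit_r), mean(fit_p$fit_r), tolerance = 1e-8)
})
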