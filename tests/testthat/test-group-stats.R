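test_that("pointwise t-tests match stats::t.test and algebraic identities", {
  set.seed(12)
  a <- matrix(rnorm(8 * 5), 8)
  b <- matrix(rnorm(8 * 5), 8)
  res <- pointwise_ttest(a, b, paired = TRUE)
  for (j in 1:5) {
    tt <- t.test(a[, j], b[, j], paired = TRUE)
    expect_equal(res$t[j], unname(tt$statistic))
    expect_equal(res$p[j], tt$p.value)
  }
  resw <- pointwise_ttest(a, b, paired = FALSE)
  for (j in 1:5) {
    tt <- t.test(a[, j], b[, j])
    expect_equal(resw$t[j], unname(tt$statistic))
    expect_equal(resw$df[j], unname(tt$parameter))
  }
  # identical sets -> t = 0, p = 1
  r0 <- pointwise_ttest(a, a, paired = TRUE)
  expect_true(all(r0$t == 0))
  expect_true(all(r0$p == 1))
  # constant-offset identity: paired t on (a + d, a) equals one-sample on d
  d <- 0.7
  r1 <- pointwise_ttest(a + d, a, paired = TRUE)
  expect_true(all(!is.finite(r1$t) | abs(r1$t) > 1e6))  # zero-variance diffs
  r2 <- pointwise_ttest(a + d + matrix(rnorm(40, sd = 0.1), 8), a, paired = TRUE)
  expect_true(all(r2$t > 0))
  expect_error(pointwise_ttest(a[1:2, ], b[1:2, ], paired = TRUE),
               "insufficient")
})

test_that("paired t on hand-sized data matches the textbook formula", {
  x <- c(12.1, 14.3, 11.8, 13.0, 12.9)
  y <- c(11.0, 13.1, 12.2, 12.0, 12.4)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  res <- pointwise_ttest(matrix(x), matrix(y), paired = TRUE)
  expect_equal(res$t, t_hand)
  expect_equal(res$df, 4)
})

test_that("BH correction equals the brute-force step-up oracle", {
  brute_bh <- function(p, alpha) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    k <- which(ps <= alpha * seq_len(m) / m)
    rej <- logical(m)
    if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  set.seed(13)
  for (i in 1:100) {
    m <- sample(c(1, 5, 20, 100), 1)
    p <- switch(sample(3, 1), runif(m), rbeta(m, 0.3, 3),
                round(runif(m), 2))
    res <- fdr_bh(p, alpha = 0.05)
    expect_identical(res$reject, brute_bh(p, 0.05))
  }
  expect_equal(fdr_bh(0.03)$p_adjusted, 0.03)           # m = 1: unchanged
  expect_equal(fdr_bh(rep(0.01, 10))$p_adjusted, rep(0.01, 10))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
  # rejections monotone in alpha
  p <- runif(50)
  r1 <- fdr_bh(p, alpha = 0.01)$reject
  r2 <- fdr_bh(p, alpha = 0.10)$reject
  expect_true(all(r2[r1]))
})

test_that("window means average inclusive lag samples", {
  lag_ms <- seq(0, 700, by = 100)
  arr <- array(0, c(2, 8, 3))
  arr[1, , ] <- 5                                   # constant -> 5
  arr[2, , 1] <- seq_along(lag_ms)                  # ramp -> midpoint
  wm <- window_mean(arr, 300, 500, lag_ms = lag_ms)
  expect_equal(wm[1, ], rep(5, 3))
  expect_equal(wm[2, 1], 5)    # samples 4,5,6 of the ramp
  # hand-built 5-sample window
  v <- c(2, 4, 6, 8, 10)
  arr2 <- array(v, c(1, 5, 1))
  expect_equal(window_mean(arr2, 0, 400, lag_ms = seq(0, 400, 100))[1, 1],
               mean(v))
  expect_error(window_mean(arr, 900, 950, lag_ms = lag_ms), "empty")
})

test_that("identical groups produce no clusters", {
  set.seed(14)
  a <- array(rnorm(10 * 4 * 20), c(10, 4, 20))
  ct <- cluster_permutation(a, a, channel_adjacency(4), n_perm = 100,
                            paired = TRUE, seed = 1)
  expect_length(ct$clusters, 0)
})

test_that("cluster members are contiguous and stats are their t-sums", {
  set.seed(15)
  a <- array(rnorm(12 * 6 * 30), c(12, 6, 30))
  b <- array(rnorm(12 * 6 * 30), c(12, 6, 30))
  a[, 2:4, 10:18] <- a[, 2:4, 10:18] + 2.5
  ct <- cluster_permutation(a, b, channel_adjacency(6), n_perm = 200,
                            paired = FALSE, seed = 2)
  expect_gt(length(ct$clusters), 0)
  for (k in seq_along(ct$clusters)) {
    mem <- ct$clusters[[k]]
    expect_equal(ct$statistic[k],
                 sum(ct$t_map[as.matrix(mem)]))
    expect_true(all(ct$p_value[k] > 0 & ct$p_value[k] <= 1))
    # contiguity: every member (beyond the first) adjoins another member
    if (nrow(mem) > 1) {
      adj <- channel_adjacency(6)
      ok <- vapply(seq_len(nrow(mem)), function(i) {
        any(vapply(seq_len(nrow(mem))[-i], function(j) {
          (mem$channel[i] == mem$channel[j] &&
             abs(mem$lag[i] - mem$lag[j]) == 1) ||
            (mem$lag[i] == mem$lag[j] &&
               adj[mem$channel[i], mem$channel[j]])
        }, logical(1)))
      }, logical(1))
      expect_true(all(ok))
    }
  }
  # the injected patch should be detected
  expect_lte(min(ct$p_value), 0.05)
  # determinism
  ct2 <- cluster_permutation(a, b, channel_adjacency(6), n_perm = 200,
                             paired = FALSE, seed = 2)
  expect_identical(ct$p_value, ct2$p_value)
})

test_that("small paired designs fall back to exhaustive sign-flip enumeration", {
  set.seed(16)
  a <- array(rnorm(6 * 3 * 10), c(6, 3, 10))
  b <- a + array(rnorm(6 * 3 * 10, 1.5), c(6, 3, 10))
  ct <- cluster_permutation(a, b, channel_adjacency(3), n_perm = 500,
                            paired = TRUE, seed = 3)
  expect_equal(ct$n_perm, 2^6)
  expect_identical(ct$p_value,
                   cluster_permutation(a, b, channel_adjacency(3),
                                       n_perm = 500, paired = TRUE,
                                       seed = 99)$p_value)
})

test_that("statistics are invariant to subject order within groups", {
  set.seed(17)
  a <- array(rnorm(9 * 4 * 12), c(9, 4, 12))
  b <- array(rnorm(9 * 4 * 12), c(9, 4, 12))
  res1 <- pointwise_ttest(matrix(a, 9), matrix(b, 9), paired = FALSE)
  res2 <- pointwise_ttest(matrix(a, 9)[sample(9), ], matrix(b, 9)[sample(9), ],
                          paired = FALSE)
  expect_equal(res1$t, res2$t)
})

test_that("correlation screen matches hand computation and Bonferroni gate", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(corr_screen(x, 2 * x + 1)$r, 1)
  y <- c(2.0, 1.0, 4.0, 3.0, 6.0)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- corr_screen(x, y, m_tests = 4)
  expect_equal(res$r, r_hand)
  expect_equal(res$alpha_adjusted, 0.0125)
  set.seed(18)
  big <- corr_screen(rnorm(1000), rnorm(1000))
  expect_lt(abs(big$r), 0.08)
  expect_error(corr_screen(x, rep(1, 5)), "degenerate")
  expect_error(corr_screen(1:3, 1:3), "at least 4")
})

test_that("one-sample t from summaries behaves like the textbook statistic", {
  expect_equal(one_sample_t(0.5, 0.1, 10, 0.5)$t, 0)
  t1 <- one_sample_t(1, 2, 16, 0)$t
  t2 <- one_sample_t(1, 4, 16, 0)$t
  expect_equal(t1, 2 * t2)           # doubling s halves t
  expect_error(one_sample_t(1, 0, 10, 0), "degenerate")
})

test_that("adjacency helpers produce symmetric neighbor graphs", {
  adj <- channel_adjacency(5)
  expect_true(isSymmetric(adj))
  expect_false(any(diag(adj)))
  expect_equal(sum(adj), 2 * 4)
  xy <- cbind(c(0, 1, 2, 10), c(0, 0, 0, 0))
  a2 <- adjacency_from_coords(xy, scale = 1.5)
  expect_true(a2[1, 2] && a2[2, 3])
  expect_false(a2[3, 4])
  expect_true(isSymmetric(a2))
})
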