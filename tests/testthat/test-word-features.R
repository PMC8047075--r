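test_that("semantic dissimilarity matches hand-computed correlations", {
  # 3-word toy sentence with hand-written 3-dim vectors
  emb <- rbind(alpha = c(1, 0, 1), beta = c(0, 1, 1), gamma = c(2, 1, 0))
  ev <- toy_events(c(0.1, 0.5, 0.9), words = c("alpha", "beta", "gamma"),
                   sentence_idx = c(1, 1, 1))
  d <- semantic_dissimilarity(ev, emb)
  # word 2: context = alpha
  expect_equal(d[2], 1 - cor(c(0, 1, 1), c(1, 0, 1)))
  # word 3: context = mean(alpha, beta) = (0.5, 0.5, 1)
  expect_equal(d[3], 1 - cor(c(2, 1, 0), c(0.5, 0.5, 1)))
  # word 1 has no context at all -> mean of the others
  expect_equal(d[1], mean(d[2:3]))
})

test_that("dissimilarity spans [0, 2] at the correlation extremes", {
  emb <- rbind(w1 = c(1, 2, 3), same = c(2, 4, 6),        # r = +1 with w1
               anti = c(3, 2, 1),                          # r = -1 with w1
               orth = c(1, 0, 1))                          # r = 0 with w1
  expect_equal(cor(emb["w1", ], emb["orth", ]), 0)
  ev <- toy_events(c(0.1, 0.5), words = c("w1", "same"), sentence_idx = c(1, 1))
  expect_equal(semantic_dissimilarity(ev, emb)[2], 0)
  ev$word <- c("w1", "anti")
  expect_equal(semantic_dissimilarity(ev, emb)[2], 2)
  ev$word <- c("w1", "orth")
  expect_equal(semantic_dissimilarity(ev, emb)[2], 1)
})

test_that("sentence-initial words use the previous sentence's mean vector", {
  set.seed(1)
  emb <- matrix(rnorm(5 * 6), 5, dimnames = list(paste0("w", 1:5), NULL))
  ev <- toy_events(seq(0.1, 0.9, by = 0.2), words = paste0("w", 1:5),
                   sentence_idx = c(1, 1, 1, 2, 2))
  d <- semantic_dissimilarity(ev, emb)
  expect_equal(d[4], 1 - cor(emb["w4", ], colMeans(emb[1:3, ])))
  # scale invariance of Pearson correlation
  d2 <- semantic_dissimilarity(ev, emb * 37.5)
  expect_equal(d, d2)
  expect_true(all(d >= 0 & d <= 2))
})

test_that("unknown and degenerate embeddings are handled per policy", {
  emb <- rbind(a = c(1, 2, 3), b = c(3, 1, 2), flat = c(1, 1, 1))
  ev <- toy_events(c(0.1, 0.5, 0.9), words = c("a", "b", "zzz"),
                   sentence_idx = c(1, 1, 1))
  expect_error(semantic_dissimilarity(ev, emb), "missing embedding.*zzz")
  d <- semantic_dissimilarity(ev, emb, unknown = "impute")
  expect_length(d, 3)
  expect_true(all(is.finite(d)))
  expect_equal(d[3], d[2])   # imputed from the sentence's known words
  ev2 <- toy_events(c(0.1, 0.5), words = c("a", "flat"), sentence_idx = c(1, 1))
  expect_error(semantic_dissimilarity(ev2, emb), "zero-variance")
})

test_that("surprisal follows the negative log10 product rule", {
  expect_equal(word_surprisal(1.0), 0)
  expect_equal(word_surprisal(0.1), 1.0)
  expect_equal(word_surprisal(c(0.1, 0.1)), 2.0)
  expect_equal(word_surprisal(c(0.5, 0.2)), 1.0)   # -log10(0.1)
  expect_error(word_surprisal(c(0.5, 0)), "0, 1")
  expect_error(word_surprisal(1.2), "0, 1")
})

test_that("surprisal is additive over concatenated token lists", {
  set.seed(2)
  for (i in 1:20) {
    p1 <- runif(sample(1:3, 1)); p2 <- runif(sample(1:3, 1))
    expect_equal(word_surprisal(c(p1, p2)),
                 word_surprisal(p1) + word_surprisal(p2))
  }
})

test_that("audibility is the RMS ratio in dB, antisymmetric under swap", {
  ev <- toy_events(c(0.1, 0.6), durations = 0.3)
  au <- gen_two_speaker_audio(ev, ev, 8000, seed = 5,
                              rms_a = c(0.2, 0.3), rms_b = c(0.02, 0.3))
  aud <- word_audibility(au, ev)
  expect_equal(aud[1], 20, tolerance = 1e-6)   # 10:1 RMS ratio -> 20 dB
  expect_equal(aud[2], 0, tolerance = 1e-6)
  expect_equal(word_audibility(au, ev, target = "b"), -aud, tolerance = 1e-6)
})

test_that("silent masker yields +Inf, later clipped to 10 dB", {
  fs <- 1000
  ev <- toy_events(0.1, durations = 0.2)
  au <- structure(list(wave_a = c(numeric(100), rnorm(200), numeric(100)),
                       wave_b = numeric(400), sample_rate_hz = fs),
                  class = "audio_pair")
  aud <- word_audibility(au, ev)
  expect_identical(aud, Inf)
  expect_equal(scale_audibility(aud), 1)
  au$wave_a <- numeric(400)
  expect_error(word_audibility(au, ev), "undefined audibility")
})

test_that("audibility scaling clips to [-10, 10] and maps to [0, 1]", {
  expect_equal(scale_audibility(0), 0.5)
  expect_equal(scale_audibility(25), 1.0)
  expect_equal(scale_audibility(-25), 0.0)
  expect_equal(scale_audibility(c(-10, 5, 10)), c(0, 0.75, 1))
})

test_that("RMS normalization sets nonzero RMS to 1 and keeps zeros", {
  expect_equal(as.numeric(rms_normalize(c(2, 2, 2))), c(1, 1, 1))
  v <- rms_normalize(c(3, 4))
  expect_equal(as.numeric(v), c(3, 4) / sqrt(12.5))
  expect_equal(sqrt(mean(v^2)), 1, tolerance = 1e-12)
  expect_equal(as.numeric(rms_normalize(c(0, 5, 0))), c(0, 1, 0))
  expect_error(rms_normalize(c(0, 0)), "degenerate")
})

test_that("impulse regressors land on the nearest sample and sum collisions", {
  ev <- toy_events(0.5)
  r <- build_regressor(ev, 1, sample_rate = 10, n_samples = 20)
  expect_equal(which(r != 0), 6)   # sample index 5 (0-based) = 6 (1-based)
  expect_equal(r[6], 1)
  expect_equal(build_regressor(toy_events(numeric(0)), numeric(0), 10, 15),
               numeric(15))
  ev2 <- toy_events(c(0.50, 0.54))
  r2 <- build_regressor(ev2, c(1, 2), sample_rate = 10, n_samples = 20)
  expect_equal(sum(r2 != 0), 1)
  expect_equal(r2[6], 3)           # collision -> summed
  ev3 <- toy_events(5)
  expect_error(build_regressor(ev3, 1, 10, 20), "outside")
})

test_that("word_regressors normalizes each feature across the recording", {
  s <- small_sim()
  reg <- word_regressors(s$ev, s$ft, s$cfg$sample_rate_hz,
                         block_duration_s = s$cfg$block_duration_s,
                         n_blocks = s$cfg$n_blocks)
  for (f in reg$features) {
    nz <- reg$values[reg$values[, f] != 0, f]
    expect_lte(length(nz), nrow(s$ev))
    expect_equal(sqrt(mean(nz^2)), 1, tolerance = 1e-9)
  }
  # onset impulses are unit amplitude after normalization
  on <- reg$values[reg$values[, "onset"] != 0, "onset"]
  expect_true(all(abs(on[on < 1.5] - 1) < 1e-9))  # collisions aside
})
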