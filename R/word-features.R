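#' Semantic dissimilarity of each word from its sentence context
#'
#' For every word, dissimilarity = 1 - correlation between the word's
#' embedding vector and the average embedding of all preceding words in the
#' same sentence. A sentence-initial word is compared against the previous
#' sentence's average vector. The very first word of the recording has no
#' context and receives the mean dissimilarity of all other words.
#'
#' @param events data frame with columns `word` and `sentence_idx`
#'   (nondecreasing).
#' @param table embedding matrix with words as row names (see
#'   [gen_embedding_table()]).
#' @param method `"pearson"` (default, correlation over vector components)
#'   or `"cosine"`.
#' @param unknown how to treat words missing from `table`: `"error"`
#'   (default) or `"impute"` (sentence-mean dissimilarity; such words are
#'   also excluded from context averages).
#' @return Numeric vector in \[0, 2\], one value per word.
#' @export
semantic_dissimilarity <- function(events, table,
                                   method = c("pearson", "cosine"),
                                   unknown = c("error", "impute")) {
  method <- match.arg(method)
  unknown <- match.arg(unknown)
  if (nrow(events) < 1) stop("no words")
  known <- events$word %in% rownames(table)
  if (!all(known) && unknown == "error") {
    stop("missing embedding for word(s): ",
         paste(unique(events$word[!known]), collapse = ", "))
  }
  simil <- function(x, y) {
    if (method == "pearson") {
      if (sd(x) == 0 || sd(y) == 0) {
        stop("undefined correlation: zero-variance embedding vector")
      }
      cor(x, y)
    } else {
      sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    }
  }
  n <- nrow(events)
  vals <- rep(NA_real_, n)
  prev_mean <- NULL
  for (s in unique(events$sentence_idx)) {
    ids <- which(events$sentence_idx == s)
    ok <- known[ids]
    vecs <- matrix(NA_real_, length(ids), ncol(table))
    if (any(ok)) vecs[ok, ] <- table[events$word[ids[ok]], , drop = FALSE]
    for (j in seq_along(ids)) {
      ctx <- if (j == 1) prev_mean else {
        prior <- vecs[seq_len(j - 1), , drop = FALSE]
        prior <- prior[stats::complete.cases(prior), , drop = FALSE]
        if (nrow(prior)) colMeans(prior) else prev_mean
      }
      if (!is.null(ctx) && ok[j]) {
        vals[ids[j]] <- 1 - simil(vecs[j, ], ctx)
      }
    }
    sv <- vecs[stats::complete.cases(vecs), , drop = FALSE]
    if (nrow(sv)) prev_mean <- colMeans(sv)
  }
  # context-free and unknown words: sentence-mean, then global-mean fallback
  if (anyNA(vals)) {
    for (i in which(is.na(vals))) {
      same <- vals[events$sentence_idx == events$sentence_idx[i]]
      vals[i] <- if (any(!is.na(same))) mean(same, na.rm = TRUE) else NA
    }
    vals[is.na(vals)] <- mean(vals, na.rm = TRUE)
  }
  vals
}

#' Lexical surprisal of a word from its token probabilities
#'
#' The probability of a word is the product of the conditional
#' probabilities of its constituent tokens; surprisal is the negative
#' log10 of that product, so it is additive over tokens and nonnegative.
#'
#' @param token_probs numeric vector of conditional probabilities, each in
#'   (0, 1\].
#' @return Scalar surprisal, `-log10(prod(token_probs))`.
#' @export
word_surprisal <- function(token_probs) {
  if (length(token_probs) == 0) stop("no token probabilities supplied")
  if (any(token_probs <= 0) || any(token_probs > 1)) {
    stop("token probabilities must lie in (0, 1]")
  }
  sum(-log10(token_probs))
}

#' Word-by-word audibility in dB SNR
#'
#' For each word of the target speaker, audibility is 20 * log10 of the
#' ratio of the target waveform's RMS over the word interval to the
#' competing speaker's RMS over the same interval. A silent masker yields
#' +Inf (and a silent target -Inf); these sentinels are resolved by
#' [scale_audibility()], which clips to +/-10 dB.
#'
#' @param audio an `audio_pair` (see [gen_two_speaker_audio()]).
#' @param events `word_events` of the target speaker.
#' @param target which waveform carries the target words: `"a"` or `"b"`.
#' @return Numeric vector of dB SNR values (possibly +/-Inf).
#' @export
word_audibility <- function(audio, events, target = c("a", "b")) {
  target <- match.arg(target)
  y <- if (target == "a") audio$wave_a else audio$wave_b
  z <- if (target == "a") audio$wave_b else audio$wave_a
  fs <- audio$sample_rate_hz
  n <- length(y)
  vapply(seq_len(nrow(events)), function(i) {
    i0 <- floor(events$onset_s[i] * fs) + 1
    i1 <- min(ceiling(events$offset_s[i] * fs), n)
    if (i0 > n || i1 < i0) stop("word interval outside audio support")
    ry <- sqrt(mean(y[i0:i1]^2))
    rz <- sqrt(mean(z[i0:i1]^2))
    if (ry == 0 && rz == 0) stop("undefined audibility: both waveforms silent")
    20 * log10(ry / rz)
  }, numeric(1))
}

#' Rescale audibility from dB SNR to \[0, 1\]
#'
#' Values are clipped to \[-10, 10\] dB and mapped linearly by
#' `(Aud + 10) / 20`. Infinite sentinels clip to 0 or 1.
#'
#' @param db_values numeric vector of dB SNR values (may contain +/-Inf).
#' @return Numeric vector in \[0, 1\].
#' @export
scale_audibility <- function(db_values) {
  (pmin(pmax(db_values, -10), 10) + 10) / 20
}

#' Normalize nonzero feature amplitudes to unit RMS
#'
#' Divides the nonzero entries by their root-mean-square so that, after
#' scaling, the nonzero values have RMS 1; zeros (the silent samples of an
#' impulse regressor) are untouched. Brings features with different value
#' ranges onto a common amplitude scale before ridge regression.
#'
#' @param values numeric vector of feature amplitudes.
#' @return The rescaled vector, with the divisor in `attr(, "rms")`.
#' @export
rms_normalize <- function(values) {
  nz <- values != 0
  if (!any(nz)) stop("degenerate feature: all values are zero")
  r <- sqrt(mean(values[nz]^2))
  out <- values
  out[nz] <- values[nz] / r
  attr(out, "rms") <- r
  out
}

#' Build an impulse regressor sampled at the EEG rate
#'
#' Zeros everywhere except at the sample nearest each word onset (ties
#' round down), which holds that word's feature value; two words mapping
#' to the same sample have their values summed, preserving total regressor
#' energy.
#'
#' @param events data frame with an `onset_s` column (seconds from segment
#'   start).
#' @param values per-word amplitudes, same length as `nrow(events)`.
#' @param sample_rate sampling rate in Hz.
#' @param n_samples length of the output series.
#' @return Numeric vector of length `n_samples`.
#' @export
build_regressor <- function(events, values, sample_rate, n_samples) {
  stopifnot(length(values) == nrow(events))
  out <- numeric(n_samples)
  if (nrow(events) == 0) return(out)
  idx <- ceiling(events$onset_s * sample_rate - 0.5) + 1  # nearest, ties down
  bad <- idx < 1 | idx > n_samples
  if (any(bad)) {
    stop("word onset(s) outside sampled range: ",
         paste(events$word[bad], collapse = ", "))
  }
  agg <- tapply(values, idx, sum)
  out[as.integer(names(agg))] <- agg
  out
}

#' Build the full word-feature regressor bundle for a recording
#'
#' Builds one impulse regressor per feature (word onset with unit
#' amplitudes; dissimilarity, surprisal and scaled audibility with their
#' per-word values), block by block, and RMS-normalizes each feature's
#' nonzero amplitudes across the whole recording.
#'
#' @param events `word_events` with a `block` column; onsets relative to
#'   block start.
#' @param features `feature_table` row-aligned with `events`.
#' @param sample_rate sampling rate in Hz.
#' @param block_duration_s duration of each block in seconds.
#' @param n_blocks number of blocks (defaults to `max(events$block)`).
#' @param normalize apply [rms_normalize()] per feature (default TRUE).
#' @return A [regressor_set()] with features `onset`, `dissimilarity`,
#'   `surprisal`, `audibility`.
#' @export
word_regressors <- function(events, features, sample_rate, block_duration_s,
                            n_blocks = max(events$block), normalize = TRUE) {
  cols <- c(onset = "onset_feature", dissimilarity = "dissimilarity",
            surprisal = "surprisal", audibility = "audibility_scaled")
  nspb <- round(block_duration_s * sample_rate)
  ntot <- nspb * n_blocks
  vals <- matrix(0, ntot, length(cols), dimnames = list(NULL, names(cols)))
  bounds <- cbind(start = (seq_len(n_blocks) - 1L) * nspb + 1L,
                  end = seq_len(n_blocks) * nspb)
  for (b in seq_len(n_blocks)) {
    sel <- events$block == b
    if (!any(sel)) next
    rows <- seq.int(bounds[b, 1], bounds[b, 2])
    for (j in seq_along(cols)) {
      vals[rows, j] <- build_regressor(events[sel, , drop = FALSE],
                                       features[[cols[j]]][sel],
                                       sample_rate, nspb)
    }
  }
  nc <- NULL
  if (normalize) {
    nc <- numeric(length(cols))
    names(nc) <- names(cols)
    for (j in seq_along(cols)) {
      v <- rms_normalize(vals[, j])
      nc[j] <- attr(v, "rms")
      vals[, j] <- v
    }
  }
  regressor_set(vals, sample_rate, bounds, norm_constants = nc)
}
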