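# File formats: word/feature tables and regressors travel as TSV (full
# "%.17g" precision so round trips are bit-exact), EEG as a float32 matrix
# with a JSON sidecar, audio as WAV (PCM16 or float32).

fmt_num <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15 & is.finite(x),
         sprintf("%.0f", x), sprintf("%.17g", x))
}

write_tsv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write / read a word-event (+ feature) table as TSV
#'
#' @param events data frame of word events, optionally with feature
#'   columns.
#' @param path file path.
#' @return `read_word_table` returns the data frame; numeric columns
#'   round-trip bit-exactly.
#' @export
write_word_table <- function(events, path) write_tsv_exact(events, path)

#' @rdname write_word_table
#' @export
read_word_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a regressor bundle (TSV values + JSON metadata)
#'
#' @param reg a [regressor_set()].
#' @param prefix path prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @return `read_regressors` returns the [regressor_set()]; values
#'   round-trip bit-exactly.
#' @export
write_regressors <- function(reg, prefix) {
  write_tsv_exact(as.data.frame(reg$values), paste0(prefix, ".tsv"))
  meta <- list(features = reg$features, sample_rate_hz = reg$sample_rate_hz,
               block_bounds = reg$block_bounds,
               norm_constants = as.list(reg$norm_constants))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
}

#' @rdname write_regressors
#' @export
read_regressors <- function(prefix) {
  vals <- as.matrix(read.delim(paste0(prefix, ".tsv")))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  colnames(vals) <- meta$features
  nc <- unlist(meta$norm_constants)
  regressor_set(vals, meta$sample_rate_hz,
                matrix(as.integer(meta$block_bounds), ncol = 2),
                norm_constants = if (length(nc)) nc else NULL)
}

#' Write / read an EEG recording as raw float32 + JSON sidecar
#'
#' The matrix is stored column-major (sample-major: all channels of
#' sample 1, then sample 2, ...) as little-endian float32; the sidecar
#' carries the sample rate, channel labels and block boundaries.
#'
#' @param rec an [eeg_recording()].
#' @param prefix path prefix; writes `<prefix>.f32` and `<prefix>.json`.
#' @return `read_eeg_raw` returns the [eeg_recording()] (float32
#'   precision).
#' @export
write_eeg_raw <- function(rec, prefix) {
  con <- file(paste0(prefix, ".f32"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  meta <- list(sample_rate_hz = rec$sample_rate_hz,
               channel_labels = rec$channel_labels,
               n_channels = nrow(rec$data), n_samples = ncol(rec$data),
               block_bounds = rec$block_bounds)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
}

#' @rdname write_eeg_raw
#' @export
read_eeg_raw <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(paste0(prefix, ".f32"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  eeg_recording(matrix(x, meta$n_channels, meta$n_samples),
                meta$sample_rate_hz, meta$channel_labels,
                matrix(as.integer(meta$block_bounds), ncol = 2))
}

#' Write / read a mono or stereo WAV file
#'
#' Minimal RIFF/WAVE support: 16-bit PCM or 32-bit IEEE float, used to
#' exchange the paired speaker waveforms.
#'
#' @param waves numeric vector (mono) or list/matrix of equal-length
#'   channels.
#' @param path file path.
#' @param sample_rate sampling rate in Hz.
#' @param bits 16 (PCM) or 32 (float).
#' @return `read_wav` returns a list with `waves` (samples x channels
#'   matrix) and `sample_rate_hz`.
#' @export
write_wav <- function(waves, path, sample_rate, bits = 32) {
  if (is.list(waves)) waves <- do.call(cbind, waves)
  waves <- as.matrix(waves)
  nchan <- ncol(waves); nsamp <- nrow(waves)
  bytes_per <- bits / 8
  data_bytes <- nsamp * nchan * bytes_per
  fmt_code <- if (bits == 32) 3L else 1L   # IEEE float vs PCM
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(nchan, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * nchan * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(nchan * bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  inter <- as.numeric(t(waves))   # interleave channels
  if (bits == 32) {
    writeBin(inter, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(pmin(inter, 1), -1) * 32767)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt_code <- nchan <- fs <- bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, "integer", 1, size = 2, endian = "little")
      nchan <- readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      n <- size / (bits / 8)
      x <- if (fmt_code == 3) {
        readBin(con, "numeric", n, size = 4, endian = "little")
      } else {
        readBin(con, "integer", n, size = 2, endian = "little") / 32767
      }
      return(list(waves = matrix(x, ncol = nchan, byrow = TRUE),
                  sample_rate_hz = fs))
    } else readBin(con, "raw", size)
  }
}

#' Write / read an embedding table as TSV
#'
#' One row per word: the word followed by its vector components.
#' @param emb matrix with words as row names.
#' @param path file path.
#' @return `read_embedding_tsv` returns the matrix with row names.
#' @export
write_embedding_tsv <- function(emb, path) {
  df <- data.frame(word = rownames(emb), as.data.frame(unclass(emb)),
                   stringsAsFactors = FALSE)
  colnames(df) <- c("word", paste0("d", seq_len(ncol(emb))))
  write_tsv_exact(df, path)
}

#' @rdname write_embedding_tsv
#' @export
read_embedding_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$word
  dimnames(m)[[2]] <- NULL
  m
}

#' Write / read a token-probability table as TSV
#'
#' Long format: one row per (word occurrence, token), columns `word_idx`,
#' `token_idx`, `prob`.
#' @param tab a `token_prob_table`.
#' @param path file path.
#' @return `read_token_prob_tsv` returns the table.
#' @export
write_token_prob_tsv <- function(tab, path) write_tsv_exact(tab, path)

#' @rdname write_token_prob_tsv
#' @export
read_token_prob_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  class(tab) <- c("token_prob_table", "data.frame")
  tab
}
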