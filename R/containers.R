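#' Multichannel EEG recording
#'
#' Container for a continuous multichannel recording made of concatenated
#' stimulus blocks. `data` is channels x samples; `block_bounds` is a
#' two-column matrix of 1-based first/last sample indices per block, sorted
#' and non-overlapping.
#'
#' @param data numeric matrix, channels x samples.
#' @param sample_rate_hz sampling rate in Hz.
#' @param channel_labels character vector, one label per row of `data`.
#' @param block_bounds integer matrix with columns `start`, `end` (1-based,
#'   inclusive). Defaults to a single block spanning the whole recording.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sample_rate_hz, channel_labels = NULL,
                          block_bounds = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data))) {
    stop("EEG data must be a finite numeric matrix")
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("CH", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("channel_labels length must match the number of data rows")
  }
  if (is.null(block_bounds)) {
    block_bounds <- cbind(start = 1L, end = ncol(data))
  }
  block_bounds <- matrix(as.integer(block_bounds), ncol = 2,
                         dimnames = list(NULL, c("start", "end")))
  if (any(block_bounds[, 1] > block_bounds[, 2]) ||
      any(block_bounds < 1L) || any(block_bounds > ncol(data)) ||
      is.unsorted(as.vector(t(block_bounds)))) {
    stop("block_bounds must be sorted, non-overlapping and within the recording")
  }
  structure(list(data = data, sample_rate_hz = sample_rate_hz,
                 channel_labels = channel_labels,
                 block_bounds = block_bounds),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d block(s)\n",
              nrow(x$data), ncol(x$data), x$sample_rate_hz,
              nrow(x$block_bounds)))
  invisible(x)
}

n_blocks <- function(rec) nrow(rec$block_bounds)

block_idx <- function(rec, b) seq.int(rec$block_bounds[b, 1], rec$block_bounds[b, 2])

#' Bundle of sampled feature regressors
#'
#' `values` is samples x features: zeros everywhere except scaled impulses
#' at word-onset samples. Shares the block structure of the recording it is
#' aligned to.
#'
#' @param values numeric matrix, samples x features, with feature names as
#'   column names.
#' @param sample_rate_hz sampling rate in Hz.
#' @param block_bounds block boundary matrix as in [eeg_recording()].
#' @param norm_constants optional named vector of the RMS constants the
#'   nonzero impulse amplitudes were divided by (see [rms_normalize()]).
#' @return An object of class `regressor_set`.
#' @export
regressor_set <- function(values, sample_rate_hz, block_bounds = NULL,
                          norm_constants = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("feature", seq_len(ncol(values)))
  }
  if (is.null(block_bounds)) {
    block_bounds <- cbind(start = 1L, end = nrow(values))
  }
  block_bounds <- matrix(as.integer(block_bounds), ncol = 2,
                         dimnames = list(NULL, c("start", "end")))
  structure(list(values = values, features = colnames(values),
                 sample_rate_hz = sample_rate_hz, block_bounds = block_bounds,
                 norm_constants = norm_constants),
            class = "regressor_set")
}

#' @export
print.regressor_set <- function(x, ...) {
  cat(sprintf("<regressor_set> %d samples @ %g Hz: %s\n",
              nrow(x$values), x$sample_rate_hz,
              paste(x$features, collapse = ", ")))
  invisible(x)
}
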