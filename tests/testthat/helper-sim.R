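# Shared small-scale simulated dataset, built once per test run.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_blocks = 6, block_duration_s = 30,
                        sample_rate_hz = 32, n_channels = 4,
                        noise_sd = 0.3, seed = 7)
      ev <- gen_word_stream(cfg)
      ft <- gen_feature_values(ev, cfg)
      truth <- default_kernel_set(cfg$sample_rate_hz, cfg$n_channels,
                                  lag_range_ms = c(0, 500),
                                  noise_sd = cfg$noise_sd)
      sim <- simulate_eeg(ev, ft, truth, cfg)
      cache <<- list(cfg = cfg, ev = ev, ft = ft, truth = truth, sim = sim)
    }
    cache
  }
})

# one-block event table with explicit timings, for hand-built examples
toy_events <- function(onsets, durations = 0.2, words = NULL,
                       sentence_idx = NULL, block = 1) {
  n <- length(onsets)
  data.frame(block = rep_len(block, n), onset_s = onsets,
             offset_s = onsets + rep_len(durations, n),
             word = if (is.null(words)) sprintf("t%02d", seq_len(n)) else words,
             sentence_idx = if (is.null(sentence_idx)) rep_len(1, n) else sentence_idx,
             stringsAsFactors = FALSE)
}
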