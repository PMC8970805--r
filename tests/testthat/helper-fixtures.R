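# Shared fixtures: small, fast synthetic inputs built in code.

# quick low-rate trial set for I/O and shape tests
tiny_trials <- function(n_per_class = 2, seed = 1, snr_db = 5,
                        erd_depth = 0.5, duration = 2, fs = 64) {
  generate_mi_eeg(synth_config(
    n_trials_per_class = n_per_class, fs = fs, duration = duration,
    beta_freq = 20, imagery_window = c(0.5, duration - 0.5),
    erd_depth = erd_depth, snr_db = snr_db, seed = seed))
}

# small scalogram set for network tests (16x16 images keep training fast)
tiny_scalograms <- function(n_per_class = 10, erd_depth = 0.9, snr_db = 20,
                            seed = 4, size = 16) {
  ts <- generate_mi_eeg(synth_config(
    n_trials_per_class = n_per_class, erd_depth = erd_depth,
    snr_db = snr_db, seed = seed))
  batch_scalograms(ts, tfr_config(out_size = c(size, size)))
}

expect_miclass_error <- function(expr, kind) {
  expect_error(expr, class = paste0("miclass_error_", kind))
}
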