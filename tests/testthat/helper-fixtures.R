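# shared fixtures: everything is generated in code, nothing read from disk

# small noiseless two-source mixture used across fada/model-selection tests
small_mixture <- function(n_trials = 6, noise_sigma = 0, seed = 3,
                          n_samples = 350) {
  make_mixture_dataset(gait_reach_config(
    n_trials = n_trials, noise_sigma = noise_sigma, seed = seed,
    n_samples = n_samples))
}

# best circular-shift |correlation| between a fitted source and a reference
best_shift_cor <- function(fitted, reference) {
  n <- length(reference)
  ref <- reference - mean(reference)
  max(abs(vapply(0:(n - 1), function(s)
    cor(ref, fitted[((seq_len(n) - 1 + s) %% n) + 1]), numeric(1))))
}

# aligned correlations of a fitted model's sources against true waveforms
truth_source_cors <- function(model, true_sources) {
  n <- ncol(true_sources)
  fits <- vapply(model$sources, fourier_eval, numeric(n), n_samples = n)
  vapply(seq_len(nrow(true_sources)), function(tj)
    max(vapply(seq_len(ncol(fits)), function(j)
      best_shift_cor(fits[, j], true_sources[tj, ]), numeric(1))),
    numeric(1))
}
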