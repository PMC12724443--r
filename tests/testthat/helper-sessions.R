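# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fun) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fun()
  .fixture_cache[[key]]
}

# Noise-only session: no evoked response, no ECG, no breathing; a single
# nominal level so that all trials pool into one average.
noise_config <- function(seed, n_trials = 100, noise_rms = 1.5e-6) {
  synth_config(
    seed = seed,
    duration = n_trials * 0.126 + 1,
    level_grid = 73,
    abr = abr_kernel_spec(amplitude_scale = 0),
    ecg = ecg_spec(amplitude = 0),
    breathing_amplitude = 0,
    abr_band_noise_rms = noise_rms)
}

# One standard healthy session, reused across test files.
healthy_session <- function() {
  cached("healthy", function() {
    generate_session(synth_config(seed = 42, duration = 120))
  })
}

healthy_result <- function() {
  cached("healthy_result", function() run_pipeline(healthy_session()))
}

# Trial tensor of i.i.d. Gaussian trials, built directly (no generator),
# for averaging-law oracles.
gaussian_tensor <- function(n_trials, sigma = 1.5e-6, seed = 1,
                            sampling_rate = 16000) {
  set.seed(seed)
  len <- 160
  epochs <- array(stats::rnorm(n_trials * len, sd = sigma),
                  dim = c(n_trials, len, 1),
                  dimnames = list(NULL, NULL, "LV"))
  structure(
    list(epochs = epochs,
         labels = data.frame(level = rep(73, n_trials),
                             polarity = rep(c(-1L, 1L),
                                            length.out = n_trials),
                             onset_sample = seq_len(n_trials)),
         include = rep(TRUE, n_trials),
         time = ((1:len) - 41) / sampling_rate,
         n_clipped = 0L,
         sampling_rate = sampling_rate,
         metadata = list(recording = "fixture")),
    class = "trial_tensor")
}
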