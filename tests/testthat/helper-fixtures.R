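# Shared fixtures, built in code at test time.

# small 4-frequency single-modality protocol
freq_protocol <- function(n_per_type, modality = "left", seed = 1) {
  types <- stimulus_types()
  generate_protocol(n_per_type = n_per_type, seed = seed,
                    types = types[types$modality == modality, ])
}

# epochs with a single channel of pure pink noise (no evoked component);
# trials are consecutive slices of one continuous stream, like real epochs
null_cz_epochs <- function(n_trials, noise_sd = 5, seed = 1) {
  X <- matrix(pink_noise(400 * n_trials, 1, noise_sd, seed = seed),
              n_trials, 400, byrow = TRUE)
  eeg_epochs(array(X, dim = c(n_trials, 1, 400)), time_ms = -50:349,
             channels = "Cz",
             labels = data.frame(frequency_hz = rep(1000L, n_trials),
                                 modality = rep("left", n_trials)))
}

# epochs with a Gaussian N100-like bump at Cz plus pink noise
bump_cz_epochs <- function(n_trials, amplitude = -8, latency = 100,
                           width = 15, noise_sd = 5, seed = 1) {
  bump <- amplitude * exp(-((-50:349) - latency)^2 / (2 * width^2))
  X <- matrix(pink_noise(400 * n_trials, 1, noise_sd, seed = seed),
              n_trials, 400, byrow = TRUE) +
    matrix(bump, n_trials, 400, byrow = TRUE)
  eeg_epochs(array(X, dim = c(n_trials, 1, 400)), time_ms = -50:349,
             channels = "Cz",
             labels = data.frame(frequency_hz = rep(1000L, n_trials),
                                 modality = rep("left", n_trials)))
}

# a tiny recording: one channel per montage row of a small montage,
# deterministic ramp voltages, events placed inside
ramp_recording <- function(n_samples = 3000, onsets_ms = c(1000, 2000)) {
  mont <- montage_subset(16)
  data <- matrix(rep(seq_len(n_samples) - 1, each = nrow(mont)),
                 nrow(mont), n_samples)
  ev <- data.frame(onset_ms = onsets_ms,
                   frequency_hz = rep(250L, length(onsets_ms)),
                   modality = rep("left", length(onsets_ms)))
  eeg_recording(data, fs_hz = 1000, channels = mont$label, events = ev,
                montage = mont)
}
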