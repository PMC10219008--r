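# Synthetic observers and small fixtures shared across the suite.
# An observer maps a waveform to a units x time activity matrix, the same
# contract layer_observer() provides for trained models.

# AC component of the Hilbert envelope
env_ac <- function(wave) {
  env <- hilbert_decompose(wave)$env
  env - mean(env)
}

# Separable oracle: unit 1 tracks envelope variance (large when modulated),
# unit 2 carries the raw (modulation-blind) waveform as a noise channel.
envelope_power_observer <- function(wave) {
  e <- env_ac(wave)
  rbind(e^2, as.numeric(wave))
}

# Information-free observer: features are leading carrier samples, which are
# independent of whether the stimulus is modulated.
first_samples_observer <- function(wave) {
  cbind(as.numeric(wave)[1:2])  # 2 units x 1 time step
}

# Observer with an internal 16 Hz low-pass on the envelope plus a noise
# channel: its detectability of AM falls off above the corner, so measured
# thresholds must rise with rate.
lowpass_env_observer <- function(corner_hz = 16, noise_gain = 1) {
  function(wave) {
    e <- waveform(env_ac(wave), sample_rate(wave))
    lp <- as.numeric(bandpass_fft(e, 0, corner_hz))
    rbind(lp^2, noise_gain * as.numeric(wave)^2)
  }
}

# small broadband test condition at a low sampling rate to keep FFTs cheap
test_condition <- function(sample_rate_hz = 8000, n_intervals = 2,
                           duration_s = 0.25) {
  cond <- am_conditions(sample_rate_hz = sample_rate_hz)
  cond <- cond[cond$condition == "bb_short", ]
  cond$duration_s <- duration_s
  cond$n_intervals <- as.integer(n_intervals)
  cond
}

# tiny architecture/model used by forward/training tests
tiny_arch <- function(n_categories = 3, window = 1600) {
  architecture(3, 32, c(8, 8, 8), c(16, 64, 128), n_categories, window)
}

# 3-category AM/tilt-separable toy corpus at 8 kHz (the end-to-end study
# conditions used throughout the suite)
toy_corpus_spec <- function(clips_per_category = 20, rng_seed = 101) {
  synthetic_corpus_spec(
    n_categories = 3, clips_per_category = clips_per_category,
    sample_rate_hz = 8000, clip_duration_s = 0.5,
    mod_center_hz = c(4, 32, 256), carrier_tilt_db_oct = c(-12, 0, 12),
    mod_depth = 0.9, target_rms = 1, rng_seed = rng_seed)
}
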