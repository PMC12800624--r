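# Shared fixtures: small, fast synthesis settings used throughout the suite.
# 8 kHz / 0.4 s keeps a full 45-call pool + feature extraction under a second
# while leaving room for 4 formants below Nyquist.

# test-local seed scoping (the package's internal helper is not exported)
with_seed <- function(seed, code) {
  withr::local_seed(seed)
  force(code)
}

fast_config <- function(...) {
  args <- utils::modifyList(
    list(sample_rate_hz = 8000, duration_s = 0.4,
         formant_centers_hz = c(500, 1100, 2100, 3100),
         formant_bandwidths_hz = c(120, 150, 200, 250)),
    list(...))
  do.call(synth_call_config, args)
}

fast_settings <- function(...) {
  frame_settings(frame_length_samples = 512, ...)
}

# Clean tone: no jitter, no noise, flat f0 - analytically known pitch.
tone_config <- function(f0 = 200, duration_s = 0.5, sr = 8000) {
  synth_call_config(sample_rate_hz = sr, duration_s = duration_s,
                    f0_base_hz = f0, f0_slope_hz_per_s = 0, jitter_cv = 0,
                    snr_db = Inf,
                    formant_centers_hz = c(500, 1100, 2100, 3100),
                    formant_bandwidths_hz = c(120, 150, 200, 250))
}

# Unfiltered sinusoid as a raw waveform (bypasses the synthesiser).
sine_wave <- function(freq, duration_s = 0.5, sr = 8000, call_id = "tone") {
  t <- seq(0, duration_s, length.out = round(duration_s * sr))
  waveform(0.8 * sin(2 * pi * freq * t), sr, call_id = call_id)
}

nine_subjects <- function() {
  data.frame(subject_id = sprintf("S%02d", 1:9),
             sex = rep(c("female", "male"), length.out = 9),
             stringsAsFactors = FALSE)
}

# A full synthetic playback campaign: pool at the empirical study's sizes,
# 12 stimuli per condition, 9 subjects x 8 sessions.
paper_scale_design <- function(seed = 1) {
  eff <- default_context_effects(include_grunt = TRUE)
  pool <- generate_call_dataset(
    5, 3, eff, seed = seed, base_config = fast_config(),
    n_per_context = c(grunt = 30, high_social = 41, low_social = 26,
                      non_social = 21))
  stim <- assemble_stimuli(pool$manifest, n_per_condition = 12, seed = seed)
  schedule_playbacks(nine_subjects(), stim, seed = seed)
}

# Gaussian feature table with a known class structure, for discriminant
# tests that do not need audio.
gaussian_feature_table <- function(n_per_class = 10, sep = 3, p = 4,
                                   classes = c("a", "b", "c"), seed = 1) {
  with_seed(seed, {
    rows <- lapply(seq_along(classes), function(i) {
      X <- matrix(rnorm(n_per_class * p), n_per_class, p)
      X[, 1] <- X[, 1] + sep * (i - 1)
      if (p >= 2) X[, 2] <- X[, 2] + sep * (i %% 2)
      df <- as.data.frame(X)
      names(df) <- paste0("feat", seq_len(p))
      df$context <- classes[i]
      df
    })
    out <- do.call(rbind, rows)
    out$call_id <- sprintf("c%03d", seq_len(nrow(out)))
    out
  })
}
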