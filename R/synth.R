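#' Configuration of the source-filter call synthesiser
#'
#' Parameters of the parametric surrogate call: a harmonic source with a
#' linear fundamental-frequency (f0) contour and cycle-wise jitter, filtered
#' through four two-pole formant resonators, shaped by an attack/decay
#' envelope and mixed with white noise at a stated signal-to-noise ratio.
#' Each field corresponds to one acoustic family that the downstream feature
#' panel measures (duration, intensity envelope, source/f0, filter/formants),
#' so each can be manipulated independently in recovery experiments.
#'
#' @param sample_rate_hz Sampling rate (Hz).
#' @param duration_s Call duration (s).
#' @param f0_base_hz Fundamental frequency at call onset (Hz).
#' @param f0_slope_hz_per_s Linear f0 drift (Hz/s); negative values fall.
#' @param jitter_cv Coefficient of variation of cycle-wise frequency jitter,
#'   in `[0, 1)`. 0 gives a perfectly periodic source.
#' @param harmonic_rolloff_db_per_octave Source spectrum slope (dB/octave);
#'   typically negative.
#' @param formant_centers_hz Four strictly increasing formant centres (Hz),
#'   all below Nyquist.
#' @param formant_bandwidths_hz Four positive formant bandwidths (Hz).
#' @param snr_db Signal-to-noise ratio of added white noise (dB); `Inf`
#'   disables noise.
#' @param envelope_attack_frac Fraction of the call spent in the onset ramp,
#'   in `(0, 1)`.
#' @return A `synth_call_config` list.
#' @export
synth_call_config <- function(sample_rate_hz = 22050,
                              duration_s = 1.2,
                              f0_base_hz = 150,
                              f0_slope_hz_per_s = -30,
                              jitter_cv = 0.03,
                              harmonic_rolloff_db_per_octave = -6,
                              formant_centers_hz = c(700, 1200, 2400, 3400),
                              formant_bandwidths_hz = c(130, 170, 220, 280),
                              snr_db = 25,
                              envelope_attack_frac = 0.15) {
  cfg <- structure(
    list(sample_rate_hz = sample_rate_hz,
         duration_s = duration_s,
         f0_base_hz = f0_base_hz,
         f0_slope_hz_per_s = f0_slope_hz_per_s,
         jitter_cv = jitter_cv,
         harmonic_rolloff_db_per_octave = harmonic_rolloff_db_per_octave,
         formant_centers_hz = formant_centers_hz,
         formant_bandwidths_hz = formant_bandwidths_hz,
         snr_db = snr_db,
         envelope_attack_frac = envelope_attack_frac),
    class = "synth_call_config"
  )
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  sr <- cfg$sample_rate_hz
  if (!is.numeric(sr) || sr <= 0) stop_invalid("sample_rate_hz must be positive")
  if (cfg$duration_s <= 0) stop_invalid("duration_s must be positive")
  if (round(cfg$duration_s * sr) < 256)
    stop_invalid("call too short: duration_s x sample_rate_hz must be >= 256 samples")
  if (cfg$f0_base_hz <= 0) stop_invalid("f0_base_hz must be positive")
  if (cfg$jitter_cv < 0 || cfg$jitter_cv >= 1)
    stop_invalid("jitter_cv must be in [0, 1)")
  fc <- cfg$formant_centers_hz
  if (length(fc) != 4L || any(fc <= 0) || any(diff(fc) <= 0))
    stop_invalid("formant_centers_hz must be 4 strictly increasing positive values")
  if (any(fc >= sr / 2))
    stop_invalid("formant centre %.0f Hz is at or above Nyquist (%.0f Hz)",
                 max(fc), sr / 2)
  if (length(cfg$formant_bandwidths_hz) != 4L || any(cfg$formant_bandwidths_hz <= 0))
    stop_invalid("formant_bandwidths_hz must be 4 positive values")
  if (cfg$envelope_attack_frac <= 0 || cfg$envelope_attack_frac >= 1)
    stop_invalid("envelope_attack_frac must be in (0, 1)")
  invisible(cfg)
}

#' Context-dependent shifts of synthesis parameters
#'
#' Encodes how one emission context (high-social, low-social, non-social, or
#' a control call type such as a grunt) displaces the baseline synthesis
#' configuration. Each shift is additive or multiplicative on one
#' [synth_call_config] field; an empty shift list reproduces the baseline
#' exactly.
#'
#' @param context Context label.
#' @param shifts Named list; each element is `shift(value, mode)` and the name
#'   is a `synth_call_config` field.
#' @return A `context_effect` object.
#' @export
context_effect <- function(context, shifts = list()) {
  stopifnot(is.character(context), length(context) == 1L)
  for (nm in names(shifts)) {
    s <- shifts[[nm]]
    if (!is.list(s) || is.null(s$value) || !s$mode %in% c("add", "mul"))
      stop_invalid("shift '%s' must be created with shift(value, mode)", nm)
  }
  structure(list(context = context, shifts = shifts), class = "context_effect")
}

#' @rdname context_effect
#' @param value Numeric offset (additive) or factor (multiplicative); may be
#'   length 4 for the formant vectors.
#' @param mode `"add"` or `"mul"`.
#' @export
shift <- function(value, mode = c("add", "mul")) {
  list(value = value, mode = match.arg(mode))
}

#' Per-caller random acoustic offsets
#'
#' Emulates stable between-individual differences (vocal tract and source
#' differences among the recorded adult males). Offsets are drawn once per
#' caller from normal distributions and are a deterministic function of
#' `(caller_id, seed)`.
#'
#' @param caller_id Caller identifier.
#' @param seed Integer seed shared across the caller pool.
#' @param sd_f0_hz SD of the additive f0 offset (Hz).
#' @param sd_duration_s SD of the additive duration offset (s).
#' @param sd_slope SD of the additive f0-slope offset (Hz/s).
#' @param sd_log_formant SD of the log of the common formant scale factor
#'   (vocal-tract length surrogate).
#' @return A `caller_profile` object.
#' @export
caller_profile <- function(caller_id, seed, sd_f0_hz = 8, sd_duration_s = 0.08,
                           sd_slope = 5, sd_log_formant = 0.02) {
  s <- string_seed(caller_id, base_seed = seed)
  off <- with_seed(s, list(
    f0_base_hz = rnorm(1, 0, sd_f0_hz),
    duration_s = rnorm(1, 0, sd_duration_s),
    f0_slope_hz_per_s = rnorm(1, 0, sd_slope),
    formant_scale = exp(rnorm(1, 0, sd_log_formant))
  ))
  structure(list(caller_id = caller_id, seed = seed, offsets = off),
            class = "caller_profile")
}

# Apply caller offsets, then context shifts, to a baseline config.
apply_call_modifiers <- function(cfg, effect = NULL, caller = NULL) {
  if (!is.null(caller)) {
    off <- caller$offsets
    cfg$f0_base_hz <- cfg$f0_base_hz + off$f0_base_hz
    cfg$duration_s <- max(cfg$duration_s + off$duration_s, 260 / cfg$sample_rate_hz)
    cfg$f0_slope_hz_per_s <- cfg$f0_slope_hz_per_s + off$f0_slope_hz_per_s
    cfg$formant_centers_hz <- cfg$formant_centers_hz * off$formant_scale
  }
  if (!is.null(effect)) {
    for (nm in names(effect$shifts)) {
      if (is.null(cfg[[nm]]))
        stop_invalid("context shift targets unknown field '%s'", nm)
      s <- effect$shifts[[nm]]
      cfg[[nm]] <- if (s$mode == "add") cfg[[nm]] + s$value else cfg[[nm]] * s$value
    }
  }
  validate_synth_config(cfg)
  cfg
}

#' Synthesise one call
#'
#' Renders a mono waveform from a [synth_call_config] after applying caller
#' offsets and context shifts: harmonic additive source with linear f0
#' contour and cycle-wise jitter, four cascaded two-pole resonators at the
#' formant centres, an attack/decay amplitude envelope, and white noise at
#' the configured SNR. Deterministic given `seed`.
#'
#' @param config Baseline [synth_call_config].
#' @param effect Optional [context_effect].
#' @param caller Optional [caller_profile].
#' @param seed Integer seed for jitter and noise.
#' @param call_id Identifier stored on the waveform.
#' @return A [waveform].
#' @export
synth_call <- function(config, effect = NULL, caller = NULL, seed = 1L,
                       call_id = NA_character_) {
  cfg <- apply_call_modifiers(config, effect, caller)
  sr <- cfg$sample_rate_hz
  n <- round(cfg$duration_s * sr)
  t <- (seq_len(n) - 1) / sr

  with_seed(seed, {
    f0 <- pmax(cfg$f0_base_hz + cfg$f0_slope_hz_per_s * t, 20)
    # cycle-wise jitter: piecewise-constant multiplicative factor per period
    if (cfg$jitter_cv > 0) {
      phase0 <- cumsum(2 * pi * f0 / sr)
      cycle <- floor(phase0 / (2 * pi)) + 1L
      fac <- pmax(rnorm(max(cycle), 1, cfg$jitter_cv), 0.5)
      f0 <- f0 * fac[cycle]
    }
    phase <- cumsum(2 * pi * f0 / sr)

    n_harm <- max(1L, floor(0.95 * (sr / 2) / max(f0)))
    x <- numeric(n)
    for (h in seq_len(n_harm)) {
      amp <- 10 ^ (cfg$harmonic_rolloff_db_per_octave * log2(h) / 20)
      x <- x + amp * sin(h * phase)
    }

    # cascade of two-pole resonators at the formant centres
    for (j in 1:4) {
      r <- exp(-pi * cfg$formant_bandwidths_hz[j] / sr)
      theta <- 2 * pi * cfg$formant_centers_hz[j] / sr
      x <- as.numeric(stats::filter(x * (1 - r), c(2 * r * cos(theta), -r^2),
                                    method = "recursive"))
    }

    # attack / release envelope (half-cosine ramps)
    na <- max(1L, round(cfg$envelope_attack_frac * n))
    nr <- max(1L, round(0.25 * n))
    env <- rep(1, n)
    env[seq_len(na)] <- 0.5 * (1 - cos(pi * seq_len(na) / na))
    env[(n - nr + 1):n] <- env[(n - nr + 1):n] *
      0.5 * (1 + cos(pi * seq_len(nr) / nr))
    x <- x * env

    if (is.finite(cfg$snr_db)) {
      p_sig <- mean(x^2)
      x <- x + rnorm(n, 0, sqrt(p_sig / 10 ^ (cfg$snr_db / 10)))
    }
    x <- 0.9 * x / max(abs(x))
  })

  waveform(x, sr, call_id = call_id,
           caller_id = if (is.null(caller)) NA_character_ else caller$caller_id,
           context = if (is.null(effect)) NA_character_ else effect$context)
}
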