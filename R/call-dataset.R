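#' Default context effects for the simulated call pool
#'
#' Three emission contexts displace the source and filter parameters in
#' opposite directions around the low-social baseline: high-social calls are
#' longer, higher-pitched and slightly formant-shifted; non-social calls are
#' shorter, lower-pitched and fall faster. `scale = 0` removes every shift
#' (the null pipeline used for calibration); `scale = 1` is the default
#' "moderate separability" condition under which classification is clearly
#' above chance but far from perfect, matching the qualitative picture the
#' analysis is designed for.
#'
#' @param scale Nonnegative multiplier applied to all shift magnitudes.
#' @param include_grunt Also return a `grunt` control effect (shorter, flat,
#'   higher-pitched call) for playback-pool simulation.
#' @return Named list of [context_effect] objects.
#' @export
default_context_effects <- function(scale = 1, include_grunt = FALSE) {
  eff <- list(
    high_social = context_effect("high_social", list(
      f0_base_hz = shift(10 * scale, "add"),
      duration_s = shift(1 + 0.06 * scale, "mul"),
      formant_centers_hz = shift(1 + 0.015 * scale, "mul")
    )),
    low_social = context_effect("low_social", list()),
    non_social = context_effect("non_social", list(
      f0_base_hz = shift(-10 * scale, "add"),
      duration_s = shift(1 - 0.05 * scale, "mul"),
      f0_slope_hz_per_s = shift(-10 * scale, "add")
    ))
  )
  if (include_grunt) {
    eff$grunt <- context_effect("grunt", list(
      duration_s = shift(0.45, "mul"),
      f0_base_hz = shift(40, "add"),
      f0_slope_hz_per_s = shift(20, "add"),
      harmonic_rolloff_db_per_octave = shift(-4, "add")
    ))
  }
  eff
}

#' Generate a labelled pool of synthetic calls
#'
#' Produces calls for `n_callers` callers in each context, with caller random
#' offsets drawn once per caller and context shifts applied per call. The
#' manifest records, per call, the identifying labels and the true generating
#' parameters (after caller and context modification), so feature-recovery
#' tests can compare estimates against ground truth.
#'
#' @param n_callers Number of callers (>= 2).
#' @param calls_per_caller_per_context Calls per (caller, context) cell;
#'   ignored for a context listed in `n_per_context`.
#' @param context_effects Named list of [context_effect]s (the names define
#'   the contexts).
#' @param seed Integer seed.
#' @param base_config Baseline [synth_call_config].
#' @param n_per_context Optional named integer vector of per-context *total*
#'   pool sizes (e.g. the 41/26/21 pool of an empirical study); totals are
#'   spread across callers as evenly as possible.
#' @param caller_sds Optional list of arguments passed to [caller_profile].
#' @param call_sds Call-level variability: SDs of per-call random offsets
#'   applied on top of caller and context effects (additive f0 and slope
#'   offsets in Hz and Hz/s, log-scale duration and formant factors).
#'   Real call pools vary call to call within a caller and context; without
#'   this, per-cell feature distributions collapse to caller point masses
#'   and every feature fails a normality screen. Set all to 0 to disable.
#' @return List with `waveforms` (named list of [waveform]) and `manifest`
#'   (data frame: call_id, caller_id, context, duration_s, f0_base_hz,
#'   f0_slope_hz_per_s, formant scale applied, peak_amp, seed used).
#' @export
generate_call_dataset <- function(n_callers = 5,
                                  calls_per_caller_per_context = 3,
                                  context_effects = default_context_effects(),
                                  seed = 1L,
                                  base_config = synth_call_config(),
                                  n_per_context = NULL,
                                  caller_sds = list(),
                                  call_sds = list(f0_base_hz = 6,
                                                  duration_log = 0.06,
                                                  f0_slope_hz_per_s = 4,
                                                  formant_log = 0.01)) {
  if (n_callers < 2) stop_invalid("n_callers must be >= 2")
  contexts <- names(context_effects)
  if (is.null(contexts) || any(!nzchar(contexts)))
    stop_invalid("context_effects must be a named list")
  caller_ids <- sprintf("M%02d", seq_len(n_callers))
  callers <- lapply(caller_ids, function(id)
    do.call(caller_profile, c(list(caller_id = id, seed = seed), caller_sds)))
  names(callers) <- caller_ids

  rows <- list(); waves <- list(); k <- 0L
  for (ctx in contexts) {
    if (!is.null(n_per_context) && ctx %in% names(n_per_context)) {
      tot <- n_per_context[[ctx]]
      per <- rep(tot %/% n_callers, n_callers)
      extra <- tot %% n_callers
      if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    } else {
      per <- rep(calls_per_caller_per_context, n_callers)
    }
    for (ci in seq_len(n_callers)) {
      for (r in seq_len(per[ci])) {
        k <- k + 1L
        call_id <- sprintf("call_%04d", k)
        call_seed <- (as.numeric(seed) * 100003 + k * 97) %% 2147480009
        cfg_k <- with_seed(call_seed + 1, {
          ck <- base_config
          ck$f0_base_hz <- ck$f0_base_hz +
            rnorm(1, 0, call_sds$f0_base_hz %||% 0)
          ck$duration_s <- ck$duration_s *
            exp(rnorm(1, 0, call_sds$duration_log %||% 0))
          ck$f0_slope_hz_per_s <- ck$f0_slope_hz_per_s +
            rnorm(1, 0, call_sds$f0_slope_hz_per_s %||% 0)
          ck$formant_centers_hz <- ck$formant_centers_hz *
            exp(rnorm(1, 0, call_sds$formant_log %||% 0))
          ck
        })
        w <- synth_call(cfg_k, effect = context_effects[[ctx]],
                        caller = callers[[ci]], seed = call_seed,
                        call_id = call_id)
        cfg <- apply_call_modifiers(cfg_k, context_effects[[ctx]],
                                    callers[[ci]])
        waves[[call_id]] <- w
        rows[[k]] <- data.frame(
          call_id = call_id, caller_id = caller_ids[ci], context = ctx,
          duration_s = cfg$duration_s, f0_base_hz = cfg$f0_base_hz,
          f0_slope_hz_per_s = cfg$f0_slope_hz_per_s,
          f1_hz = cfg$formant_centers_hz[1], snr_db = cfg$snr_db,
          peak_amp = max(abs(w$samples)), seed = call_seed,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  list(waveforms = waves, manifest = do.call(rbind, rows))
}
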