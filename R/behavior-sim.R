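#' Configuration of the behavioural trial generator
#'
#' Effect sizes and variance components used to simulate coded playback
#' responses. Defaults are the printed mixed-model estimates of the study
#' design this simulator emulates: gaze coefficients (log scale, Poisson
#' part) and yawn coefficients (logit scale) with a shared subject random
#' intercept. The trigger-context factor is coded with `high_social` as
#' reference; `sex` enters as male = 1.
#'
#' @param beta_gaze Named coefficients on the log scale for the gaze-count
#'   mechanism: intercept, sex_male, receiver_social, trigger_low,
#'   trigger_non, trigger_grunt, trial_order.
#' @param beta_sdb Same structure for self-directed-behaviour bouts
#'   (default: intercept only, i.e. no context effect).
#' @param beta_yawn Named coefficients on the logit scale for the evoked
#'   yawn-response mechanism (same names as `beta_gaze`).
#' @param zi_prob Zero-inflation probability of the count mechanisms, in
#'   `[0, 1)`.
#' @param sigma_subject SD of the subject random intercept (shared between
#'   mechanisms).
#' @param spontaneous_yawn_rate_per_min Spontaneous yawning rate; the 3-min
#'   observation window turns it into a floor probability
#'   `1 - exp(-3 * rate)` mixed into every trial.
#' @param lambda_gaze_before,lambda_sdb_before Poisson means of the
#'   pre-stimulus 1-min baseline counts.
#' @param diff_mode `"floor0"` (default): post-stimulus count = baseline +
#'   zero-inflated Poisson increment, so the after-minus-before difference is
#'   nonnegative. `"raw"`: the post-stimulus count is itself the
#'   zero-inflated Poisson draw, so differences can be negative.
#' @return A `behavioral_gen_config` list.
#' @export
behavioral_gen_config <- function(
    beta_gaze = c(intercept = 1.192, sex_male = 0.331, receiver_social = -0.095,
                  trigger_low = 0.162, trigger_non = -0.938,
                  trigger_grunt = -0.5, trial_order = -0.184),
    beta_sdb = c(intercept = 0.3, sex_male = 0, receiver_social = 0,
                 trigger_low = 0, trigger_non = 0, trigger_grunt = 0,
                 trial_order = 0),
    beta_yawn = c(intercept = -1.786, sex_male = -1.799, receiver_social = 3.162,
                  trigger_low = -1.861, trigger_non = -2.042,
                  trigger_grunt = -1.479, trial_order = -0.184),
    zi_prob = 0.2,
    sigma_subject = 0.1876,
    spontaneous_yawn_rate_per_min = 0.25,
    lambda_gaze_before = 2,
    lambda_sdb_before = 1,
    diff_mode = c("floor0", "raw")) {
  diff_mode <- match.arg(diff_mode)
  req <- c("intercept", "sex_male", "receiver_social", "trigger_low",
           "trigger_non", "trigger_grunt", "trial_order")
  for (b in list(beta_gaze, beta_sdb, beta_yawn))
    if (!all(req %in% names(b)))
      stop_invalid("coefficient vectors need names: %s", paste(req, collapse = ", "))
  if (zi_prob < 0 || zi_prob >= 1) stop_invalid("zi_prob must be in [0, 1)")
  if (sigma_subject < 0) stop_invalid("sigma_subject must be >= 0")
  if (spontaneous_yawn_rate_per_min < 0)
    stop_invalid("spontaneous_yawn_rate_per_min must be >= 0")
  structure(list(beta_gaze = beta_gaze, beta_sdb = beta_sdb,
                 beta_yawn = beta_yawn, zi_prob = zi_prob,
                 sigma_subject = sigma_subject,
                 spontaneous_yawn_rate_per_min = spontaneous_yawn_rate_per_min,
                 lambda_gaze_before = lambda_gaze_before,
                 lambda_sdb_before = lambda_sdb_before,
                 diff_mode = diff_mode),
            class = "behavioral_gen_config")
}

trial_linear_predictor <- function(beta, sex, receiver_context,
                                   trigger_context, trial_order) {
  beta[["intercept"]] +
    beta[["sex_male"]] * (sex == "male") +
    beta[["receiver_social"]] * (receiver_context == "social") +
    beta[["trigger_low"]] * (trigger_context == "low_social") +
    beta[["trigger_non"]] * (trigger_context == "non_social") +
    beta[["trigger_grunt"]] * (trigger_context == "grunt") +
    beta[["trial_order"]] * trial_order
}

rzip <- function(n, lambda, zi) {
  ifelse(runif(n) < zi, 0L, rpois(n, lambda))
}

#' Simulate coded behavioural responses for a playback design
#'
#' For each session of the design, draws gaze and self-directed-behaviour
#' counts before and after the stimulus and the binary yawn response in the
#' 3-min post-stimulus window. One random intercept per subject is drawn
#' once and shared between the count and yawn mechanisms. The evoked yawn
#' probability is mixed with the spontaneous floor
#' `p = p_spont + (1 - p_spont) * plogis(eta + b)`, so the total probability
#' never falls below the spontaneous level. The pre-stimulus yawn field is 0
#' for every trial, emulating the exclusion criterion that trials are only
#' run when no yawn occurred shortly before the stimulus.
#'
#' @param design A `playback_design` from [schedule_playbacks].
#' @param config A [behavioral_gen_config].
#' @param seed Integer seed.
#' @return Data frame of class `behavioral_dataset`, one row per session:
#'   subject_id, sex, trial_order, receiver_context, trigger_context,
#'   gazes_before, gazes_after, sdb_before, sdb_after, yawn_before,
#'   yawn_after.
#' @export
generate_behavioral_dataset <- function(design,
                                        config = behavioral_gen_config(),
                                        seed = 1L) {
  s <- design$sessions
  with_seed(seed, {
    b <- setNames(rnorm(nrow(design$subjects), 0, config$sigma_subject),
                  design$subjects$subject_id)
    n <- nrow(s)
    bs <- b[s$subject_id]
    eta_g <- trial_linear_predictor(config$beta_gaze, s$sex,
                                    s$receiver_context, s$condition,
                                    s$trial_order) + bs
    eta_s <- trial_linear_predictor(config$beta_sdb, s$sex,
                                    s$receiver_context, s$condition,
                                    s$trial_order) + bs
    eta_y <- trial_linear_predictor(config$beta_yawn, s$sex,
                                    s$receiver_context, s$condition,
                                    s$trial_order) + bs

    gazes_before <- rpois(n, config$lambda_gaze_before)
    sdb_before <- rpois(n, config$lambda_sdb_before)
    gaze_inc <- rzip(n, exp(eta_g), config$zi_prob)
    sdb_inc <- rzip(n, exp(eta_s), config$zi_prob)
    if (config$diff_mode == "floor0") {
      gazes_after <- gazes_before + gaze_inc
      sdb_after <- sdb_before + sdb_inc
    } else {
      gazes_after <- gaze_inc
      sdb_after <- sdb_inc
    }
    p_floor <- 1 - exp(-3 * config$spontaneous_yawn_rate_per_min)
    p_yawn <- p_floor + (1 - p_floor) * stats::plogis(eta_y)
    yawn_after <- as.integer(runif(n) < p_yawn)

    out <- data.frame(
      subject_id = s$subject_id, sex = s$sex, trial_order = s$trial_order,
      receiver_context = s$receiver_context, trigger_context = s$condition,
      gazes_before = gazes_before, gazes_after = gazes_after,
      sdb_before = sdb_before, sdb_after = sdb_after,
      yawn_before = 0L, yawn_after = yawn_after,
      stringsAsFactors = FALSE
    )
  })
  class(out) <- c("behavioral_dataset", "data.frame")
  out
}

#' Subset a behavioural dataset the way the study models subset it
#'
#' Models 1-3 use only the yawn-stimulus trials (trigger context high/low/
#' non-social; the grunt control trials are excluded). Model 4 uses only the
#' grooming (social receiver context) trials in which the stimulus was a
#' high-social yawn or a grunt.
#'
#' @param trials A `behavioral_dataset` (or any data frame with its columns).
#' @param model Integer 1-4.
#' @return The subset, rows reindexed.
#' @export
model_subset <- function(trials, model) {
  stopifnot(model %in% 1:4)
  out <- if (model %in% 1:3) {
    trials[trials$trigger_context != "grunt", , drop = FALSE]
  } else {
    trials[trials$receiver_context == "social" &
             trials$trigger_context %in% c("high_social", "grunt"), ,
           drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
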