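#' Schedule playback sessions under field constraints
#'
#' Assigns every subject eight sessions — each of the four stimulus
#' conditions in each of the two receiver contexts — across consecutive
#' days, honouring the constraints a field playback campaign operates under:
#' at most three playbacks per day overall; at most one session per subject
#' per day (the 24-h spacing rule, modelled on the day scale); each stimulus
#' administered at most twice and never twice to the same subject; and no
#' subject ever hears the same call in two different stimuli.
#'
#' @param subjects Data frame with `subject_id` and `sex` columns.
#' @param stimuli A `stimulus_set` from [assemble_stimuli] covering all four
#'   conditions.
#' @param seed Integer seed.
#' @param conditions Conditions to cross with receiver contexts (default the
#'   conditions present in `stimuli`).
#' @param receiver_contexts Receiver contexts (default social / non_social).
#' @param max_per_day Global daily playback cap.
#' @param max_stim_admin Maximum administrations per stimulus.
#' @return A `playback_design`: list with `subjects`, `sessions` (data frame:
#'   subject_id, sex, day_index, condition, receiver_context, stimulus_id,
#'   trial_order) and `stimuli`.
#' @export
schedule_playbacks <- function(subjects, stimuli, seed = 1L,
                               conditions = NULL,
                               receiver_contexts = c("social", "non_social"),
                               max_per_day = 3L, max_stim_admin = 2L) {
  stopifnot(all(c("subject_id", "sex") %in% names(subjects)))
  conditions <- conditions %||% unique(stimuli$condition)
  n_cond <- length(conditions)
  per_subject <- n_cond * length(receiver_contexts)
  for (cond in conditions) {
    n_avail <- sum(stimuli$condition == cond)
    if (n_avail * max_stim_admin < length(receiver_contexts) * nrow(subjects))
      stop_infeasible(
        "condition '%s': %d stimuli x %d administrations cannot cover %d sessions",
        cond, n_avail, max_stim_admin,
        length(receiver_contexts) * nrow(subjects))
  }

  with_seed(seed, {
    pending <- lapply(seq_len(nrow(subjects)), function(i) {
      g <- expand.grid(condition = conditions,
                       receiver_context = receiver_contexts,
                       stringsAsFactors = FALSE)
      g[sample(nrow(g)), , drop = FALSE]
    })
    names(pending) <- subjects$subject_id
    admin_count <- setNames(rep(0L, nrow(stimuli)), stimuli$stimulus_id)
    heard_calls <- setNames(vector("list", nrow(subjects)), subjects$subject_id)
    heard_stimuli <- setNames(vector("list", nrow(subjects)), subjects$subject_id)
    trial_no <- setNames(rep(0L, nrow(subjects)), subjects$subject_id)

    sessions <- list(); k <- 0L; day <- 0L
    while (any(vapply(pending, nrow, 0L) > 0)) {
      day <- day + 1L
      if (day > 100L * per_subject)
        stop_infeasible("scheduling failed to terminate; constraints too tight")
      todo <- names(pending)[vapply(pending, nrow, 0L) > 0]
      todo <- sample(todo)
      slots <- min(max_per_day, length(todo))
      for (sid in todo[seq_len(slots)]) {
        pair <- pending[[sid]][1, ]
        cand <- stimuli[stimuli$condition == pair$condition, , drop = FALSE]
        ok <- vapply(cand$stimulus_id, function(st) {
          if (admin_count[st] >= max_stim_admin) return(FALSE)
          if (st %in% heard_stimuli[[sid]]) return(FALSE)
          !any(stimulus_calls(stimuli, st) %in% heard_calls[[sid]])
        }, logical(1))
        if (!any(ok))
          stop_infeasible(paste0(
            "no admissible stimulus for subject %s, condition '%s' ",
            "(binding constraint: stimulus reuse <= %d / calls never heard twice)"),
            sid, pair$condition, max_stim_admin)
        st <- sample(cand$stimulus_id[ok], 1)
        admin_count[st] <- admin_count[st] + 1L
        heard_stimuli[[sid]] <- c(heard_stimuli[[sid]], st)
        heard_calls[[sid]] <- c(heard_calls[[sid]], stimulus_calls(stimuli, st))
        trial_no[sid] <- trial_no[sid] + 1L
        k <- k + 1L
        sessions[[k]] <- data.frame(
          subject_id = sid,
          sex = subjects$sex[subjects$subject_id == sid],
          day_index = day, condition = pair$condition,
          receiver_context = pair$receiver_context,
          stimulus_id = st, trial_order = trial_no[sid],
          stringsAsFactors = FALSE
        )
        pending[[sid]] <- pending[[sid]][-1, , drop = FALSE]
      }
    }
    sessions_df <- do.call(rbind, sessions)
  })

  design <- structure(
    list(subjects = subjects, sessions = sessions_df, stimuli = stimuli,
         max_per_day = max_per_day, max_stim_admin = max_stim_admin),
    class = "playback_design"
  )
  viol <- validate_design(design)
  if (length(viol) > 0)
    stop_infeasible("generated design violates its own constraints: %s",
                    paste(viol, collapse = "; "))
  design
}

#' Re-check a playback design against every scheduling constraint
#'
#' @param design A `playback_design`.
#' @return Character vector of violated constraints (empty on success).
#' @export
validate_design <- function(design) {
  s <- design$sessions
  stimuli <- design$stimuli
  viol <- character(0)
  per_subject <- table(s$subject_id)
  n_cond <- length(unique(s$condition))
  n_recv <- length(unique(s$receiver_context))
  expected <- n_cond * n_recv
  if (any(per_subject != expected))
    viol <- c(viol, sprintf("subjects with != %d sessions: %s", expected,
                            paste(names(per_subject)[per_subject != expected],
                                  collapse = ",")))
  for (sid in unique(s$subject_id)) {
    ss <- s[s$subject_id == sid, ]
    combos <- paste(ss$condition, ss$receiver_context)
    if (anyDuplicated(combos))
      viol <- c(viol, sprintf("subject %s repeats a condition x receiver cell", sid))
    day_tab <- table(ss$day_index)
    if (any(day_tab > 1))
      viol <- c(viol, sprintf("subject %s has >1 session on a day (24-h rule)", sid))
    for (d in names(day_tab)) {
      cond_day <- ss$condition[ss$day_index == as.integer(d)]
      if (anyDuplicated(cond_day))
        viol <- c(viol, sprintf("subject %s repeats condition on day %s", sid, d))
    }
    calls <- unlist(lapply(ss$stimulus_id, stimulus_calls, stimuli = stimuli))
    if (anyDuplicated(calls))
      viol <- c(viol, sprintf("subject %s hears a call twice", sid))
  }
  day_totals <- table(s$day_index)
  if (any(day_totals > design$max_per_day))
    viol <- c(viol, sprintf(">%d playbacks on day(s) %s", design$max_per_day,
                            paste(names(day_totals)[day_totals > design$max_per_day],
                                  collapse = ",")))
  stim_admin <- table(s$stimulus_id)
  if (any(stim_admin > design$max_stim_admin))
    viol <- c(viol, sprintf("stimulus administered >%d times: %s",
                            design$max_stim_admin,
                            paste(names(stim_admin)[stim_admin > design$max_stim_admin],
                                  collapse = ",")))
  if (any(!s$stimulus_id %in% stimuli$stimulus_id))
    viol <- c(viol, "session references unknown stimulus")
  viol
}

#' @export
print.playback_design <- function(x, ...) {
  cat(sprintf("<playback_design: %d subjects, %d sessions over %d days>\n",
              nrow(x$subjects), nrow(x$sessions), max(x$sessions$day_index)))
  invisible(x)
}
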