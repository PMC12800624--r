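#' Assemble playback stimuli from a call pool
#'
#' Builds stimulus sequences of three consecutive calls of one condition,
#' separated by two pauses drawn uniformly from 5-10 s. Peak amplitudes of
#' the three calls are equalised (gain factors are reported; audio is not
#' re-rendered). Re-use is constrained the way field playback pools are
#' built: each call may appear in at most `max_call_reuse` distinct stimuli
#' and the same 3-call combination is never used twice.
#'
#' @param manifest Pool manifest: data frame with `call_id`, `context`,
#'   `duration_s` and optionally `peak_amp` columns.
#' @param n_per_condition Number of stimuli requested per condition.
#' @param conditions Conditions to assemble (default: all contexts present).
#' @param seed Integer seed.
#' @param max_call_reuse Maximum number of stimuli a call may appear in.
#' @return Data frame of class `stimulus_set`: stimulus_id, condition,
#'   call_id_1..3, gain_1..3, pause_1_s, pause_2_s, total_duration_s.
#' @export
assemble_stimuli <- function(manifest, n_per_condition, conditions = NULL,
                             seed = 1L, max_call_reuse = 2L) {
  stopifnot(all(c("call_id", "context", "duration_s") %in% names(manifest)))
  conditions <- conditions %||% unique(manifest$context)
  if (!"peak_amp" %in% names(manifest)) manifest$peak_amp <- 1
  use_count <- setNames(rep(0L, nrow(manifest)), manifest$call_id)
  combos_seen <- character(0)

  with_seed(seed, {
    out <- list(); k <- 0L
    for (cond in conditions) {
      pool <- manifest[manifest$context == cond, , drop = FALSE]
      if (nrow(pool) < 3)
        stop_infeasible("condition '%s' has %d calls; need at least 3",
                        cond, nrow(pool))
      capacity <- floor(max_call_reuse * nrow(pool) / 3)
      if (n_per_condition > capacity)
        stop_infeasible(paste0(
          "call reuse limit (<= %d stimuli per call) allows at most %d ",
          "stimuli for condition '%s'; %d requested"),
          max_call_reuse, capacity, cond, n_per_condition)
      for (i in seq_len(n_per_condition)) {
        picked <- NULL
        for (attempt in 1:1000) {
          avail <- pool$call_id[use_count[pool$call_id] < max_call_reuse]
          if (length(avail) < 3)
            stop_infeasible(
              "call reuse limit (<= %d uses) exhausted for condition '%s'",
              max_call_reuse, cond)
          # least-used calls first (random tie-break) so that exact-capacity
          # requests pack instead of dead-ending
          cand <- avail[order(use_count[avail], runif(length(avail)))][1:3]
          key <- paste(sort(cand), collapse = "|")
          if (!key %in% combos_seen) { picked <- cand; combos_seen <- c(combos_seen, key); break }
        }
        if (is.null(picked))
          stop_infeasible(
            "could not find an unused 3-call combination for condition '%s'",
            cond)
        use_count[picked] <- use_count[picked] + 1L
        durs <- pool$duration_s[match(picked, pool$call_id)]
        peaks <- pool$peak_amp[match(picked, pool$call_id)]
        pauses <- runif(2, 5, 10)
        k <- k + 1L
        out[[k]] <- data.frame(
          stimulus_id = sprintf("stim_%03d", k), condition = cond,
          call_id_1 = picked[1], call_id_2 = picked[2], call_id_3 = picked[3],
          gain_1 = max(peaks) / peaks[1], gain_2 = max(peaks) / peaks[2],
          gain_3 = max(peaks) / peaks[3],
          pause_1_s = pauses[1], pause_2_s = pauses[2],
          total_duration_s = sum(durs) + sum(pauses),
          stringsAsFactors = FALSE
        )
      }
    }
    res <- do.call(rbind, out)
  })
  class(res) <- c("stimulus_set", "data.frame")
  attr(res, "call_use_count") <- use_count[use_count > 0]
  res
}

stimulus_calls <- function(stimuli, stimulus_id) {
  row <- stimuli[stimuli$stimulus_id == stimulus_id, , drop = FALSE]
  c(row$call_id_1, row$call_id_2, row$call_id_3)
}
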