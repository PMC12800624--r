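#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`, then
#' restores the previous RNG state, so that simulation helpers are
#' deterministic without clobbering the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Stable small integer hash of a string, used to derive per-entity seeds.
# Kept below 2^31 so the result is a valid R integer seed.
string_seed <- function(x, base_seed = 0L) {
  codes <- utf8ToInt(as.character(x))
  h <- 0
  for (ci in codes) h <- (h * 31 + ci) %% 2147480009
  as.integer((h + as.numeric(base_seed) * 7919) %% 2147480009)
}

stop_invalid <- function(fmt, ...) {
  stop(structure(
    class = c("callcontext_invalid_config", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

stop_infeasible <- function(fmt, ...) {
  stop(structure(
    class = c("callcontext_infeasible", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
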