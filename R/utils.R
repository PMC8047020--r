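#' Experimental group labels
#'
#' The six experimental groups of the TAC time course: sham controls and
#' cells collected 3 days and 1, 2, 4 and 8 weeks after transverse aortic
#' constriction.
#'
#' @return Character vector of group labels in temporal order.
#' @export
timecourse_groups <- function() c("sham", "D3", "W1", "W2", "W4", "W8")

#' TAC (non-sham) group labels in temporal order
#' @return Character vector of the five post-surgery time points.
#' @export
tac_groups <- function() c("D3", "W1", "W2", "W4", "W8")

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Stable 32-bit-safe integer seed derived from a global seed and a stage name.
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

# Lightweight info logging used by readers and pipeline stages.
log_info <- function(...) message(sprintf(...))

`%||%` <- function(a, b) if (is.null(a)) b else a
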