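# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations in the
# package route through this so that a function's output depends only on its
# arguments.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a master seed
#'
#' Hashes a stage name together with a master seed so that every stochastic
#' pipeline stage gets its own reproducible stream, and adding a stage never
#' perturbs the seeds of existing ones. The result is always a positive
#' integer below 2^31.
#'
#' @param master Single integer master seed.
#' @param stage Character scalar naming the stage.
#' @return A positive integer seed.
#' @export
#' @examples
#' derive_seed(1, "decompose")
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer(((abs(master) %% 2147483647) * 69069 + h * 7919 + 1) %% 2147483646 + 1)
}

# round-half-up, as opposed to base round()'s round-half-even
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

EMOTIONS   <- c("angry", "happy", "sad")
CONDITIONS <- c("expression_only", "emotive_speech")
SUBSTATES  <- c("relaxed", "sustain", "transition")
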