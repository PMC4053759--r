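#' Derive a reproducible sub-seed for a named simulation stage
#'
#' All randomness in the package flows from a single user seed. Each stage
#' (genealogy, clonal substitutions, imports, gene flux, dropout, reads, EM
#' restarts) draws from its own stream, derived deterministically from the
#' master seed and the stage name, so stages can be re-run independently and
#' changing one stage's draws never perturbs another's.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @param counter optional integer counter (e.g. replicate index).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage, counter = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% 2147483647
  s <- (abs(seed) %% 2147483647)
  as.integer((s * 48271 + h * 69621 + abs(counter) * 16807 + 1) %% 2147483647)
}

# Evaluate expr under a stage-derived seed, restoring the caller's RNG state.
with_stage_seed <- function(seed, stage, expr, counter = 0L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stage_seed(seed, stage, counter))
  expr
}
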