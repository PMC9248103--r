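#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds R's generator, evaluates `expr`, and
#' restores the previous state, so seeded helpers never perturb the session
#' stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-participant seed from a master seed by counter splitting
#'
#' A fixed integer hash (two rounds of the minimal-standard multiplier after
#' an affine counter mix) maps `(master, i)` to a stream seed, so that
#' participant i's draws are unchanged when the cohort grows or shrinks.
#' All arithmetic stays below 2^53 and results are in \[1, 2^31 - 2\].
#'
#' @param master Master integer seed.
#' @param i Non-negative counter (participant index or stream id).
#' @return Integer seed for `set.seed()`.
#' @keywords internal
derive_seed <- function(master, i) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.numeric(master)) + as.numeric(i) * 2654435) %% (m - 1) + 1
  s <- (s * 16807) %% m
  s <- (s * 16807) %% m
  as.integer(s)
}
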