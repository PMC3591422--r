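#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded package functions never disturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a per-item seed from a master seed
#'
#' Deterministic integer hash of (master seed, index) used to give each tree
#' in a sample its own randomization seed, so per-tree results do not depend
#' on execution order. Stays within the 32-bit signed-integer range.
#'
#' @param master_seed integer master seed.
#' @param index 1-based item index.
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(master_seed, index) {
  # multiplicative hash mod 2^31 - 1 (a Mersenne prime), done in doubles to
  # avoid integer overflow; inputs are small integers
  m <- 2147483647
  h <- (as.numeric(master_seed) %% m) * 48271 %% m
  h <- (h + as.numeric(index) * 16807) %% m
  as.integer((h * 69621) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
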