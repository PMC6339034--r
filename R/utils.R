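# Internal helpers: condition constructors, seeded evaluation, small numerics.

#' Signal a classed riemgait error
#'
#' All package errors carry class `riemgait_error` plus a specific subclass
#' (`riemgait_error_<what>`) so callers and tests can discriminate failure
#' modes without matching message text.
#'
#' @param msg message string.
#' @param class specific subclass suffix, e.g. "format".
#' @noRd
rg_stop <- function(msg, class) {
  stop(errorCondition(
    msg,
    class = c(paste0("riemgait_error_", class), "riemgait_error")
  ))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Clamp to [-1, 1] before acos; floating-point safety near parallel vectors.
clamp1 <- function(x) pmin(1, pmax(-1, x))

vnorm <- function(v) sqrt(sum(v * v))

# Derive a stream-specific 32-bit seed from a base seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
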