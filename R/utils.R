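# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate expr with a locally set RNG seed, restoring the caller's RNG state.
# All generators funnel randomness through this so they are pure functions of
# (params, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and an index, kept below 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) * 1103L + as.integer(k) * 12347L) %% 2147483587L
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_nfb <- function(fmt, ..., class = "nfbloop_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}
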