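#' @keywords internal
"_PACKAGE"

## Seed handling: every stochastic entry point takes an integer `seed`.
## Evaluation restores the caller's RNG state afterwards so library calls
## never clobber a user's stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

## Deterministic sub-stream seeds derived from a global seed.  Kept below
## 2^31 - 1 so they remain valid R integers.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 9349) %% 2147483563) + 1L
}

clip01 <- function(x) pmin(1, pmax(0, x))

stop_octa <- function(code, msg, ...) {
  cond <- structure(
    class = c(code, "octaquant_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
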