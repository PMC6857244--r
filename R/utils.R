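#' @importFrom methods new validObject is slot
#' @importFrom stats runif rnorm rbinom rpois median
#' @importFrom utils read.table write.table head tail
NULL

## Evaluate expr under a given RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Derive an independent per-stream seed from a base seed (kept < 2^31).
streamSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 9973) %% 2147483587L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
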