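#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif rnorm setNames quantile ks.test median sd
#' @importFrom utils read.delim write.table head tail
NULL

# Classed error helper so callers can test on condition class.
pd_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "promdiag_error")))
}

# Derive a reproducible 32-bit sub-seed from a master seed and an offset.
# Linear-congruential mix keeps streams for different offsets decoupled
# while staying inside R's integer range.
derive_seed <- function(seed, offset) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 69069 + as.double(offset) * 104729 + 12345) %% 2147483647
  as.integer(x)
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
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

`%||%` <- function(a, b) if (is.null(a)) b else a
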