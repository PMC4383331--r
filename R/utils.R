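# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so package functions never leak global RNG
#' side effects.  All stochastic functions in the package take an
#' explicit `seed` and route through this helper.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize a RNG state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Convert a time in ms to a sample count at rate fs.  One rounding
# convention for the whole package: round-half-to-even (base round()).
ms_to_samples <- function(ms, fs) {
  as.integer(round(ms / 1000 * fs))
}

samples_to_ms <- function(n, fs) {
  n / fs * 1000
}

# Quantize to the nearest single-precision float, elementwise.  Used by
# the generator so fixture round trips (stored as float32) are lossless.
as_float32 <- function(x) {
  d <- dim(x)
  out <- readBin(writeBin(as.vector(x), raw(), size = 4), "double",
                 n = length(x), size = 4)
  dim(out) <- d
  out
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
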