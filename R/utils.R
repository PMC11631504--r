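# Internal helpers shared across modules.

# Evaluate `code` under a given RNG seed without clobbering the caller's
# RNG state. All exported functions that take a `seed` argument route
# their randomness through this.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic sub-seed derivation: bounded below 2^31 regardless of the
# top-level seed the caller passes.
deriveSeed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) + 7919L * as.integer(stream)
}

asMatrix <- function(X, arg = "X") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop(sprintf("'%s' must be a numeric matrix", arg))
  if (any(!is.finite(X)))
    stop(sprintf("'%s' contains non-finite values", arg))
  X
}

asNumericVector <- function(y, arg = "y") {
  y <- as.numeric(y)
  if (any(!is.finite(y)))
    stop(sprintf("'%s' contains non-finite values", arg))
  y
}
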