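# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route their randomness through
# this, so a given (function, seed) pair is bit-reproducible and no call
# disturbs global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a per-item child seed from a base seed; stays below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483629)
}

stopifnot_same_grid <- function(dims_a, dims_b, what = "volumes") {
  if (length(dims_a) != length(dims_b) || any(dims_a != dims_b))
    stop(sprintf("%s are on different grids: %s vs %s", what,
                 paste(dims_a, collapse = "x"), paste(dims_b, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}
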