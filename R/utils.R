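#' @keywords internal
"_PACKAGE"

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
# All stochastic functions in the package route their randomness through
# this so that no call mutates global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  force(code)
}

# Derive a child seed from a parent seed and a stream index; keeps every
# consumer of randomness on a named, reproducible stream within 32-bit range.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 69621) %% 2147483399 + 1
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`", name, "` must be a single finite number")
  }
  invisible(x)
}
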