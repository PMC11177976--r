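# Internal helpers: seeded evaluation and seed-stream derivation.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive `n` independent sub-seeds from a master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  local_seed(seed, as.list(sample.int(2147483646L, n)))
}

stop_invalid <- function(...) stop(..., call. = FALSE)

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_scalar_num <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
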