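# Internal helpers shared across modules.

# Round half away from zero (round-half-up for non-negative input).
# base::round() rounds half to even, which would make item discretization
# depend on parity of the latent value.
round_half_up <- function(x) floor(x + 0.5)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic operations in the package
# route their seed through this helper so that no call mutates global state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and an index, staying within the
# 32-bit integer range R requires for set.seed().
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1009 + index * 9973) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
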