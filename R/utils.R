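# internal helpers shared across the package

# Round half away from zero. base::round() rounds half to even, which would
# turn a requested sample size of 0.5 into 0; proportional sample sizes must
# round 0.5 up so a block is never left without a reference sample.
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Run `code` under `seed` without disturbing the caller's RNG stream.
# With seed = NULL the current stream is used (and advanced), matching the
# convention of stats::simulate().
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("`seed` must be a single finite number", call. = FALSE)
    }
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = env)
      } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    })
    set.seed(as.integer(seed))
  }
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
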