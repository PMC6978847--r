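# Per-task RNG substreams: each binary task carries its own saved
# .Random.seed so results do not depend on how tasks are interleaved.

rng_make <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  s <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  s
}

# Run fn() under the given RNG state; returns its value and the advanced
# state, restoring whatever state the caller had.
with_rng <- function(state, fn) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", state, envir = globalenv())
  value <- fn()
  new_state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  list(value = value, state = new_state)
}

# Seeds drawn for substreams stay below 2^31 (R integers are 32-bit).
draw_subseeds <- function(n) sample.int(2147483646L, n)
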