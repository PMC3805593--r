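# Seed plumbing. All stochastic entry points take an integer seed and
# evaluate under with_seed(), which restores the caller's RNG state, so a
# cohort seed fully determines every draw without side effects.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Documented derivation: child seed = (a * P1 + b * P2 + c) mod (2^31 - 1),
# with distinct odd multipliers per level. Keeps derived seeds within the
# 32-bit integer range R requires.
derive_seed <- function(master, a = 0L, b = 0L) {
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 48271
  s <- (s + as.numeric(a) * 69621 + as.numeric(b) * 16807 + 1) %% m
  as.integer(s)
}
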