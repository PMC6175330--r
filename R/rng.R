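# Deterministic child-seed derivation so that each participant, subrun and
# noise source has its own reproducible stream hanging off one root seed.

# Mix a root seed with one or more integer indices through a few rounds of a
# 31-bit linear congruential scramble (Park-Miller multiplier). Output is a
# positive integer < 2^31 suitable for set.seed().
childSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  if (s == 0) s <- 1
  for (i in idx) {
    s <- (s * 48271 + as.double(i) + 1) %% 2147483647
    s <- (s * 48271 + 11) %% 2147483647
  }
  as.integer(if (s == 0) 1 else s)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
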