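# Independent RNG streams derived from one master seed.
#
# The two dishes (and the exchange-jitter source) each own a private RNG
# state, so dish-A trajectories are unchanged by dish-B settings. States are
# snapshots of .Random.seed swapped in and out around each draw.

make_stream <- function(seed) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  st <- new.env(parent = emptyenv())
  st$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  st
}

with_stream <- function(stream, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  expr
}

# Derive k child seeds from a master seed without disturbing the caller's
# RNG state. Kept below 2^31 - 1.
derive_seeds <- function(seed, k) {
  st <- make_stream(seed)
  with_stream(st, sample.int(.Machine$integer.max - 1L, k))
}
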