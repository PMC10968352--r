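# internal helpers: seed management and small utilities

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr                     # promise evaluates in the caller's environment
}

# deterministic child-seed derivation: mixes a master seed with integer tags
# (participant index, run index, repeat index, ...) into a 31-bit seed.
# splitmix-style multiply/xor mixing keeps children well separated.
child_seed <- function(master, ...) {
  tags <- c(...)
  h <- as.double(master) %% 2147483647
  for (t in c(tags, 0x9E37)) {
    h <- (h * 48271 + as.double(t) * 16807 + 12345) %% 2147483647
    h <- (h * 69621) %% 2147483647
  }
  as.integer(h)
}

# evenly-spaced deterministic subsample of a vector (at most n points)
thin_to <- function(x, n) {
  if (length(x) <= n) return(x)
  x[round(seq(1, length(x), length.out = n))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
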