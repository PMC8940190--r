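# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never disturbs the
# user's random stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

# deterministic checksum of a numeric vector, computed on the IEEE-754 byte
# representation so it detects any bit-level change; vectorized (no digest dep)
hash_samples <- function(x) {
  b <- as.integer(writeBin(as.numeric(x), raw(), size = 8))
  w <- (seq_along(b) - 1) %% 251 + 1
  s1 <- sum(b * w) %% 4294967291
  s2 <- sum(b * rev(w)) %% 4294967291
  sprintf("%.0f-%.0f", s1, s2)
}
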