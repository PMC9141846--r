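## Internal helpers.

## Evaluate expr with the RNG seeded to `seed`, restoring the caller's
## RNG state afterwards so package functions never disturb the session.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Deterministic child seed below 2^31, derived from a base seed and
## integer tags (splitmix-style multiply-xor on doubles is overkill;
## a simple affine hash mod a prime suffices for stream separation).
derive_seed <- function(seed, ...) {
  tags <- c(...)
  h <- as.numeric(seed) %% 2147483629
  for (tg in tags) h <- (h * 48271 + as.numeric(tg) + 1) %% 2147483629
  as.integer(h + 1)
}

## max |x| of a matrix difference, used in orthogonality checks
max_abs <- function(x) max(abs(x))
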