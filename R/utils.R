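# Internal helpers: deterministic RNG scoping and seed derivation.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stable 31-bit string hash (polynomial rolling hash), independent of R's
# internal hashing so batch results are reproducible across sessions.
hash_string <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483629
  as.integer(h)
}

# Derive the per-structure RNG seed from the global seed and structure id, so
# combination-cap sampling is independent of batch composition and ordering.
derive_seed <- function(global_seed, structure_id) {
  as.integer((as.numeric(global_seed) %% 2147483629 + hash_string(structure_id)) %% 2147483629)
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
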