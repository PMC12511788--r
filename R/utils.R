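# Shared helpers: reproducible RNG scoping and deterministic substreams.

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit hash of a string, for per-unit RNG substreams: the
# sample drawn inside one unit depends only on (seed, unit_id), so adding or
# removing other units/species never perturbs it.
string_hash31 <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

substream_seed <- function(seed, key) {
  as.integer((as.numeric(seed) %% 2147483647 + string_hash31(key)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
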