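# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state on
# exit so package functions never perturb the user's stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic 31-bit substream seed derived from a parent seed and integer
# keys (stream id, strain index, day ...). Lehmer-style mixing; distinct key
# tuples get effectively independent streams, and adding strains never
# perturbs the draws of earlier strains.
substream_seed <- function(seed, ...) {
  h <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (k in c(...)) {
    h <- (h * 48271 + (as.double(k) + 1) * 16807 + 11) %% 2147483647
  }
  as.integer(h)
}

# sample standard deviation with an informative error for degenerate input
sample_sd <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values", call. = FALSE)
  sd(x)
}

stop_config <- function(...) stop("configuration error: ", ..., call. = FALSE)
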