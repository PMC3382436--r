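# Internal helpers shared across the package.

# Temporarily seed the session RNG; returns a restore function for on.exit().
# Keeps user-visible RNG state untouched by package internals.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  if (!is.null(seed)) set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

# Deterministic 31-bit sub-seed from a master seed plus arbitrary string tags;
# lets folds, permutations and per-configuration runs draw independent but
# reproducible streams from one master seed.
derive_seed <- function(master, ...) {
  tags <- paste(c(as.character(master), vapply(list(...), as.character, character(1L))),
                collapse = "\r")
  h <- 5381
  for (b in utf8ToInt(tags)) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

# Binary entropy (bits) of a 0/1 label vector.
entropy01 <- function(y) {
  p <- mean(y)
  if (p <= 0 || p >= 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
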