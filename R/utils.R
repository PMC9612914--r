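# internal helpers

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb the
# global stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stable deterministic 31-bit hash of a character key; used to derive child
# seeds from (master seed, pair, study index) so corpora are extensible
# without reshuffling already generated studies.
stable_hash <- function(key) {
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

child_seed <- function(master, ...) {
  stable_hash(paste(c(master, ...), collapse = "|"))
}

stopifnot_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(what, " must be strictly positive and finite", call. = FALSE)
  }
  invisible(x)
}
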