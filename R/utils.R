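#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so library internals never disturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-case substream derivation. Products stay far below 2^53 so
# double arithmetic is exact; result is in [1, 2^31 - 20].
mix_seed <- function(seed, index, salt = 0L) {
  s <- (abs(as.numeric(seed)) %% 100003) + 1
  v <- (s * 1664525 + as.numeric(index) * 22695477 + as.numeric(salt) * 7919) %%
    2147483629
  as.integer(v + 1)
}

# clamp numeric values into [lo, hi]
clamp01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

stop_dim <- function(...) stop(..., call. = FALSE)
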