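# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls never perturb user simulations.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Largest-remainder apportionment of n items over `fractions` (sum to 1).
# Deterministic; ties on remainders resolved by position.
largest_remainder <- function(n, fractions) {
  quota <- n * fractions
  sizes <- floor(quota)
  short <- n - sum(sizes)
  if (short > 0) {
    ord <- order(quota - sizes, decreasing = TRUE)
    sizes[ord[seq_len(short)]] <- sizes[ord[seq_len(short)]] + 1L
  }
  as.integer(sizes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sg <- function(...) stop(..., call. = FALSE)
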