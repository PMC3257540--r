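# internal helpers shared across modules

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
with_rng_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

next_pow2 <- function(n) 2L^as.integer(ceiling(log2(n)))

# signed DFT frequencies in cycles per sample for an n-point transform
fft_freq <- function(n) {
  k <- 0:(n - 1L)
  ((k + floor(n / 2)) %% n - floor(n / 2)) / n
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
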