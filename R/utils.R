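# Internal helpers.

# Prefix-stable stream of per-bivalent seeds from one user seed, via a
# Lehmer multiplicative generator (modulus 2^31 - 1, multiplier 48271).
# Exact in doubles (products < 2^53). Because bivalent i always receives
# the i-th element, enlarging a simulation never perturbs earlier bivalents.
bfSeedStream <- function(seed, n) {
  m <- 2147483647
  s <- as.double(seed) %% m
  if (s <= 0) s <- s + m - 1
  out <- numeric(n)
  for (k in seq_len(n)) {
    s <- (48271 * s) %% m
    out[k] <- s
  }
  as.integer(out)
}

bfResolveSeed <- function(seed) {
  if (is.null(seed))
    seed <- sample.int(2147483646L, 1L)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be coercible to an integer")
  seed
}

# Save/restore the global RNG state so seeded simulations do not disturb
# the caller's random stream.
bfSaveRNG <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

bfRestoreRNG <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Wilson 95% score interval for a binomial proportion.
wilsonInterval <- function(x, n, conf = 0.95) {
  if (n <= 0) return(c(lower = NA_real_, upper = NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

bfScalarProb <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(name, " must be a single value in [0, 1]")
  as.numeric(x)
}
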