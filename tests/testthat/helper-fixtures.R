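# Shared fixtures and independent oracles for the test suite.

# The hand-checkable 4-bivalent CoC example: with two intervals, both
# interval frequencies are 3/4, observed doubles 1/2, expected 9/16,
# CoC = 8/9.
toyCoCSet <- function() {
  bivalentSet(list(c(0.25, 0.75), c(0.25, 0.75), 0.25, 0.75),
              lengthsUm = 1)
}

# Independent brute-force CoC oracle: explicit loops over bivalents and
# interval pairs, no shared code with computeCoC().
cocOracle <- function(positions, K) {
  n <- length(positions)
  pres <- matrix(FALSE, n, K)
  for (b in seq_len(n)) {
    for (p in positions[[b]]) {
      k <- min(floor(p * K) + 1, K)
      pres[b, k] <- TRUE
    }
  }
  f <- colSums(pres) / n
  rows <- list()
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      expd <- f[i] * f[j]
      if (expd == 0) next
      obs <- sum(pres[, i] & pres[, j]) / n
      rows[[length(rows) + 1]] <-
        data.frame(i = i, j = j, distance = (j - i) / K,
                   observed = obs, expected = expd, coc = obs / expd)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$distance, out$i), , drop = FALSE]
}

# Independent designation oracle: ramp the driving force in small steps,
# designating any precursor whose requirement is met, most-reactive first.
rampOracle <- function(arr, params, thresholds, dS = 1e-3) {
  x <- arr@positions
  cracks <- numeric(0)
  ord <- integer(0)
  remaining <- seq_along(x)
  for (S in seq(dS, params@Smax, by = dS)) {
    repeat {
      if (!length(remaining)) break
      R <- reliefMultiplier(x[remaining], cracks, params)
      sreq <- ifelse(R > 0, thresholds[remaining] / R, Inf)
      m <- which.min(sreq)
      if (sreq[m] > S) break
      ord <- c(ord, remaining[m])
      cracks <- c(cracks, x[remaining[m]])
      remaining <- remaining[-m]
    }
  }
  ord
}

randomArray <- function(n) {
  new("PrecursorArray", positions = sort(runif(n)),
      sensitivities = pmin(pmax(runif(n), 1e-6), 1 - 1e-6))
}
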