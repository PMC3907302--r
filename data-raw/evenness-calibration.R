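# Generates the evenness calibration table shipped in R/precursors.R.
#
# The placement model mixes sorted-uniform positions with the even grid
# g_i = (i - 0.5)/n using weight w. This script finds, by bisection, the
# weights at which the maximum-likelihood gamma shape of pooled interior
# inter-precursor gaps (13 precursors per bivalent, 5000 bivalents, fixed
# seed) equals the anchor values nu = 2.4 (E = 0.6) and nu = 4.2 (E = 0.7).
# E = 0 maps to w = 0 (nu = 1) and E = 1 to w = 1 (exact grid). Run with:
#   Rscript data-raw/evenness-calibration.R
suppressPackageStartupMessages(library(beamfilm))

nuAtW <- function(w, n = 13, nBiv = 5000, seed = 20140130) {
  set.seed(seed)
  gaps <- unlist(lapply(seq_len(nBiv), function(i) {
    u <- sort(runif(n))
    g <- (seq_len(n) - 0.5) / n
    diff((1 - w) * u + w * g)
  }))
  fitGamma(gaps)$shape
}

calibrate <- function(target, lo = 0, hi = 0.95) {
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (nuAtW(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < 5e-6) break
  }
  (lo + hi) / 2
}

w06 <- calibrate(2.4)
w07 <- calibrate(4.2)
cat(sprintf("w(E = 0.6) = %.5f (nu = %.3f)\n", w06, nuAtW(w06)))
cat(sprintf("w(E = 0.7) = %.5f (nu = %.3f)\n", w07, nuAtW(w07)))
cat("paste into .evennessTable in R/precursors.R:\n")
cat(sprintf("  w = c(0, %.5f, %.5f, 1)\n", w06, w07))
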