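test_that("the four-bivalent example reproduces the hand-computed CoC", {
  cc <- computeCoC(toyCoCSet(), nIntervals = 2)
  pairs <- cocPairs(cc)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$observed, 0.5)
  expect_equal(pairs$expected, 0.5625)
  expect_equal(pairs$coc, 8 / 9)
  expect_equal(cocCurve(cc)$distance, 0.5)
})

test_that("computeCoC agrees exactly with a brute-force pair-counting oracle", {
  set.seed(41)
  for (rep in 1:3) {
    pos <- lapply(rpois(40, 3), function(k) sort(runif(k)))
    data <- bivalentSet(pos, lengthsUm = 2.5)
    K <- sample(5:12, 1)
    got <- suppressWarnings(cocPairs(computeCoC(data, nIntervals = K)))
    want <- cocOracle(pos, K)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("independent COs give CoC near 1 at every distance", {
  set.seed(42)
  pois <- bivalentSet(lapply(rpois(10000, 4), function(k) sort(runif(k))),
                      lengthsUm = 1)
  cc <- suppressWarnings(computeCoC(pois, nIntervals = 10))
  expect_true(all(abs(cocCurve(cc)$coc - 1) < 0.1))
})

test_that("interference produces the classical CoC curve shape", {
  p <- bfPresets("yeastXV")
  s <- simulateBF(p$spec, p$precursor, p$patterning, 1, 4000, seed = 43)
  cc <- computeCoC(s, intervalUm = 0.1)
  curve <- cocCurve(cc)
  expect_lt(curve$coc[1], 0.2)          # strong short-range suppression
  expect_gt(max(curve$coc), 1)          # overshoot near the mean spacing
  expect_false(is.na(lCoC(cc)))
})

test_that("L_CoC interpolates the first upward crossing of 0.5", {
  mk <- function(d, v)
    new("CoCCurve",
        pairs = data.frame(i = integer(0), j = integer(0),
                           distance = numeric(0), observed = numeric(0),
                           expected = numeric(0), coc = numeric(0)),
        curve = data.frame(distance = d, distanceUm = d * 2, coc = v,
                           nPairs = rep(1L, length(d))),
        intervalSize = 0.1, nIntervals = 10L, lengthUm = 2)
  expect_equal(lCoC(mk(c(0.2, 0.3), c(0.4, 0.6))), 0.25)
  expect_equal(lCoC(mk(c(0.2, 0.3), c(0.4, 0.6)), unit = "um"), 0.5)
  expect_true(is.na(lCoC(mk(c(0.1, 0.2, 0.3), c(1, 1, 1)))))
  expect_true(is.na(lCoC(mk(c(0.1, 0.2), c(0.4, 0.45)))))
})

test_that("the event distribution summarises counts with a Wilson interval", {
  ones <- bivalentSet(as.list(runif(50)), lengthsUm = 1)
  ed <- eventDistribution(ones)
  expect_equal(ed$mean, 1)
  expect_equal(ed$zeroFraction, 0)
  expect_equal(sum(ed$histogram$fraction), 1)
  expect_true(ed$zeroCI[["upper"]] > 0)  # Wilson upper bound is positive
})

test_that("maturation thinning matches the binomial convolution oracle", {
  p <- bfPresets("yeastXV")
  full <- simulateBF(p$spec, p$precursor, p$patterning, 1, 6000, seed = 44)
  half <- simulateBF(p$spec, p$precursor, p$patterning, 0.5, 6000, seed = 44)
  edF <- eventDistribution(full)
  edH <- eventDistribution(half)
  expect_equal(edH$mean, edF$mean / 2, tolerance = 0.03)
  # predicted thinned histogram: g(j) = sum_k f(k) C(k, j) 0.5^k
  f <- edF$histogram$fraction
  kmax <- max(edF$histogram$count)
  g <- vapply(0:kmax, function(j)
    sum(f[(j:kmax) + 1] * dbinom(j, j:kmax, 0.5)), numeric(1))
  got <- numeric(kmax + 1)
  got[edH$histogram$count + 1] <- edH$histogram$fraction
  expect_lt(max(abs(got - g)), 0.02)
})

test_that("inter-CO distances pool adjacent gaps from 2+ CO bivalents", {
  data <- bivalentSet(list(c(0.2, 0.5, 0.9), 0.4, numeric(0)),
                      lengthsUm = 10)
  expect_equal(interCODistances(data), c(0.3, 0.4))
  expect_equal(interCODistances(data, unit = "um"), c(3, 4))
})

test_that("the gamma fit recovers known shapes and cross-checks MASS", {
  set.seed(45)
  expect_equal(fitGamma(rexp(1e5))$shape, 1, tolerance = 0.02)
  expect_equal(fitGamma(rgamma(1e5, shape = 3))$shape, 3, tolerance = 0.05)
  expect_error(fitGamma(rexp(5)), "at least 10")

  d <- rgamma(5000, shape = 2.2, scale = 0.4)
  ours <- fitGamma(d)
  ref <- MASS::fitdistr(d, "gamma")
  expect_equal(ours$shape, unname(ref$estimate["shape"]), tolerance = 0.01)
  expect_equal(1 / ours$scale, unname(ref$estimate["rate"]),
               tolerance = 0.01)
})

test_that("position histograms expose end clamping and density holes", {
  set.seed(46)
  flat <- bivalentSet(lapply(rpois(4000, 4), function(k) sort(runif(k))),
                      lengthsUm = 1)
  h <- positionHistogram(flat, nBins = 10)
  expect_lt(diff(range(h$freq)) / mean(h$freq), 0.25)

  s <- simulateBF(chromosomeSpec(1), precursorParams(8, E = 0, B = 1),
                  patterningParams(Smax = 3.5, L = 0.3, A = 1,
                                   cL = 1, cR = 1),
                  1, 4000, seed = 47)
  hc <- positionHistogram(s, nBins = 10)
  expect_gt(hc$freq[1], 1.15 * mean(hc$freq[4:7]))
  expect_gt(hc$freq[10], 1.15 * mean(hc$freq[4:7]))

  g <- bfPresets("grasshopperL3")
  sg <- simulateBF(g$spec, g$precursor, g$patterning, 1, 1500, seed = 48)
  hg <- positionHistogram(sg, nBins = 20)
  expect_equal(hg$freq[10], 0)
  expect_equal(hg$freq[11], 0)

  h2 <- positionHistogram(sg, nBins = 10, byRank = TRUE, coClass = 2)
  expect_setequal(unique(h2$rank), 1:2)
  expect_equal(sum(h2$freq[h2$rank == 1]), 1)
})

test_that("centromere-spanning pairs reproduce the full CoC curve", {
  g <- bfPresets("grasshopperL3")
  sg <- simulateBF(g$spec, g$precursor, g$patterning, 1, 4000, seed = 12)
  full <- computeCoC(sg, nIntervals = 17)
  expect_identical(cocSubsetSpanning(sg, NULL, nIntervals = 17)@curve,
                   full@curve)
  span <- cocSubsetSpanning(sg, region = c(0.45, 0.55), nIntervals = 17)
  expect_true(all(cocPairs(span)$i <= 8 & cocPairs(span)$j >= 10))
  m <- merge(cocCurve(full), cocCurve(span), by = "distance")
  expect_lt(mean(abs(m$coc.x - m$coc.y)), 0.2)
  # region covering everything leaves only the outermost pair
  whole <- cocSubsetSpanning(sg, region = c(0, 1), nIntervals = 17)
  expect_equal(cocPairs(whole)$i, 1L)
  expect_equal(cocPairs(whole)$j, 17L)
})
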