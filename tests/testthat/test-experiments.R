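specU <- chromosomeSpec(1)

test_that("homeostasis interpolates between proportional and buffered regimes", {
  pr <- precursorParams(8, E = 0, B = 1)
  pt <- patterningParams(Smax = 3.5, L = 1e-9, A = 1, cL = 1, cR = 1)
  sw <- homeostasisSweep(specU, pr, pt, 1, NValues = c(4, 8, 16),
                         LValues = c(1e-9, 100), nBivalents = 3000,
                         seed = 51, referenceN = 8)
  none <- sw[sw$L < 1e-6, ]
  # no interference: CO levels proportional to precursor levels
  expect_equal(none$meanCO[none$N == 16] / none$meanCO[none$N == 4], 4,
               tolerance = 0.1)
  # closed form at L = 0 with fully clamped ends: N * P(designation)
  pd <- 1 - integrate(function(s) exp(-3.5 * s^2), 0, 1)$value
  expect_equal(none$meanCO[none$N == 8], 8 * pd, tolerance = 0.03)
  # very long interference distance: CO levels flat in N
  huge <- sw[sw$L == 100, ]
  expect_lt(diff(range(huge$meanCO)) / mean(huge$meanCO), 0.1)
  # CO per precursor non-increasing in N at fixed positive L
  sw2 <- homeostasisSweep(specU, pr,
                          patterningParams(Smax = 3.5, L = 0.2, A = 1,
                                           cL = 1, cR = 1),
                          1, NValues = c(4, 8, 16), LValues = 0.2,
                          nBivalents = 3000, seed = 52, referenceN = 8)
  expect_true(all(diff(sw2$coPerPrecursor[order(sw2$N)]) < 0))
  expect_equal(sw2$relCO[sw2$N == 8], 1)
})

test_that("zero-CO sweeps expose the parameter dependencies", {
  pr <- precursorParams(8, E = 0.6, B = 1)
  pt <- patterningParams(Smax = 5, L = 0.1, A = 1, cL = 0.85, cR = 0.85)
  # thinning closed form: zero(M) = sum_k f(k) (1-M)^k of the M = 1 ED
  full <- simulateBF(specU, pr, pt, 1, 5000, seed = 53)
  ed <- eventDistribution(full)
  predicted <- sum(ed$histogram$fraction * 0.7^ed$histogram$count)
  swM <- zeroCOSweep(specU, pr, pt, 1, "M", 0.3, nBivalents = 5000,
                     seed = 53)
  expect_equal(swM$zeroFraction, predicted, tolerance = 0.15)
  # zero-CO non-increasing in N
  swN <- zeroCOSweep(specU, precursorParams(4, 0.6, 0.5),
                     patterningParams(Smax = 2.5, L = 0.1, A = 1,
                                      cL = 0.85, cR = 0.85),
                     1, "N", c(3, 6, 12), nBivalents = 5000, seed = 54)
  expect_true(all(diff(swN$zeroFraction) <= 0))
  # 2-D grid support
  sw2 <- zeroCOSweep(specU, pr, pt, 1, c("N", "Smax"),
                     expand.grid(N = c(4, 8), Smax = c(2, 5)),
                     nBivalents = 1000, seed = 55)
  expect_equal(nrow(sw2), 4)
  expect_true(all(c("N", "Smax", "zeroFraction", "zeroLower") %in%
                  names(sw2)))
})

test_that("homeostasis strength is the interference/spacing ratio", {
  expect_equal(homeostasisStrength(0.3, 0.3)$ratio, 1)
  expect_equal(homeostasisStrength(11, 0.888)$ratio, 12.387, tolerance = 1e-3)
  expect_equal(homeostasisStrength(7.7, 7.7)$ratio, 1)
  expect_error(homeostasisStrength(-1, 1))
})

test_that("the grid scan recovers parameters from self-simulated data", {
  p <- bfPresets("yeastXV")
  truth <- simulateBF(p$spec, p$precursor, p$patterning, 1, 1500, seed = 99)
  fs <- suppressWarnings(fitScan(
    truth, p$spec, p$precursor, p$patterning, 1,
    grid = list(L = c(0.05, 0.1, 0.2, 0.3), Smax = c(2.5, 3.5, 4.5)),
    nIntervals = 16, nBivalents = 1500, seed = 7))
  expect_equal(nrow(fs), 12)           # full table, never only the top hit
  best <- fs[fs$rank == 1, ]
  expect_equal(best$L, 0.1)
  expect_equal(best$Smax, 3.5)
})

test_that("the scan score vanishes for identical parameters and seed", {
  p <- bfPresets("yeastXV")
  truth <- simulateBF(p$spec, p$precursor, p$patterning, 1, 1000, seed = 99)
  fs <- suppressWarnings(fitScan(
    truth, p$spec, p$precursor, p$patterning, 1,
    grid = list(L = 0.1), nIntervals = 16, nBivalents = 1000, seed = 99))
  expect_equal(nrow(fs), 1)            # single-combination scan is legal
  expect_equal(unname(unlist(fs[1, c("cocRMSE", "dMeanCO", "edTV",
                                     "dZero")])),
               rep(0, 4))
  # mismatched chromosome lengths are rejected
  expect_error(fitScan(truth, chromosomeSpec(9), p$precursor,
                       p$patterning, 1, grid = list(L = 0.1)),
               "lengths")
})

test_that("analyzeDataset equals its parts and rejects empty input", {
  p <- bfPresets("yeastXV")
  s <- simulateBF(p$spec, p$precursor, p$patterning, 1, 800, seed = 56)
  rep <- analyzeDataset(s, intervalUm = 0.1)
  expect_equal(cocCurve(rep$coc), cocCurve(computeCoC(s, intervalUm = 0.1)))
  expect_equal(rep$ed, eventDistribution(s))
  expect_equal(rep$gamma, fitGamma(interCODistances(s)))
  expect_equal(rep$lCoCUm, rep$lCoC * scLength(s))
  expect_error(analyzeDataset(bivalentSet(list(), lengthsUm = 1)))
})
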