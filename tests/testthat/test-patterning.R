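clamped <- function(Smax = 3.5, L = 0.25, A = 1)
  patterningParams(Smax = Smax, L = L, A = A, cL = 1, cR = 1)

test_that("relief multiplier matches the stress formula", {
  pp <- clamped()
  expect_equal(reliefMultiplier(c(0.1, 0.5, 0.9), numeric(0), pp),
               c(1, 1, 1))
  # zero exactly at a designation site
  expect_equal(reliefMultiplier(0.5, cracks = 0.5, pp), 0)
  # one crack at distance L
  expect_equal(reliefMultiplier(0.25, cracks = 0.5, pp), 1 - exp(-1))
  # a free end cannot support stress
  free <- patterningParams(Smax = 3.5, L = 0.25, A = 1, cL = 0, cR = 1)
  expect_equal(reliefMultiplier(0, numeric(0), free), 0)
  # hyper-clamped end raises R above 1 nearby
  hyper <- patterningParams(Smax = 3.5, L = 0.25, A = 1, cL = 1.7, cR = 1)
  expect_gt(reliefMultiplier(0.01, numeric(0), hyper), 1)
  expect_error(reliefMultiplier(1.2, numeric(0), pp))
})

test_that("threshold scale follows the reactivity laws", {
  expect_equal(designationThreshold(0.5, 2), 2)
  expect_equal(designationThreshold(0.5, 1), 4)
  expect_equal(designationThreshold(0.5, 3), 0.1)
  expect_equal(designationThreshold(0.5, 4), 0.5)
  expect_error(designationThreshold(1.5, 1))
  expect_error(designationThreshold(0.5, 5))
})

test_that("event-driven designation equals a brute-force force ramp", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    arr <- randomArray(n)
    pp <- patterningParams(Smax = runif(1, 1, 4), L = runif(1, 0.05, 0.4),
                           A = sample(1:2, 1), cL = runif(1, 0, 1.2),
                           cR = runif(1, 0, 1.2))
    thr <- rexp(n) * designationThreshold(arr@sensitivities, pp@A)
    d <- designate(arr, pp, thresholds = thr)
    expect_identical(d$order, rampOracle(arr, pp, thr))
    # force level at each designation is non-decreasing and never over Smax
    if (length(d$sAtDesignation)) {
      expect_true(all(diff(d$sAtDesignation) >= -1e-12))
      expect_true(all(d$sAtDesignation <= pp@Smax + 1e-12))
    }
  }
})

test_that("coincident precursors yield exactly one designation", {
  arr <- new("PrecursorArray", positions = c(0.4, 0.4),
             sensitivities = c(0.9, 0.9))
  d <- designate(arr, clamped(), thresholds = c(0.01, 0.01))
  expect_length(d$designated, 1)
  expect_length(d$leftover, 1)
  # empty array is a legal zero-CO bivalent
  empty <- new("PrecursorArray", positions = numeric(0),
               sensitivities = numeric(0))
  expect_length(designate(empty, clamped())$designated, 0)
})

test_that("maturation is independent Bernoulli thinning", {
  pos <- seq(0.01, 0.99, length.out = 10)
  expect_identical(matureCOs(pos, 1), pos)
  expect_identical(matureCOs(pos, 0), numeric(0))
  expect_error(matureCOs(pos, 1.2))
  set.seed(22)
  kept <- mean(replicate(1000, length(matureCOs(pos, 0.5)))) / 10
  expect_equal(kept, 0.5, tolerance = 0.04)
})

test_that("simulation is reproducible and prefix-stable in nBivalents", {
  p <- bfPresets("yeastXV")
  s1 <- simulateBF(p$spec, p$precursor, p$patterning, 1, 50, seed = 9)
  s2 <- simulateBF(p$spec, p$precursor, p$patterning, 1, 50, seed = 9)
  expect_identical(coPositions(s1), coPositions(s2))
  s3 <- simulateBF(p$spec, p$precursor, p$patterning, 1, 120, seed = 9)
  expect_identical(coPositions(s1), coPositions(s3)[1:50])
  expect_false(identical(
    coPositions(simulateBF(p$spec, p$precursor, p$patterning, 1, 50,
                           seed = 10)),
    coPositions(s1)))
})

test_that("an unbounded driving force manifests every precursor", {
  spec <- chromosomeSpec(1)
  pr <- precursorParams(8, E = 0, B = 1)
  pt <- patterningParams(Smax = 1e9, L = 1e-9, A = 1, cL = 1, cR = 1)
  s <- simulateBF(spec, pr, pt, 1, 200, seed = 31)
  expect_true(all(coCounts(s) == 8))
  expect_true(all(lengths(s@metadata$leftoverPositions) == 0))
})

test_that("doubling the interference distance lowers CO numbers", {
  p <- bfPresets("yeastXV")
  ptHi <- p$patterning; ptHi@L <- 2 * p$patterning@L
  m1 <- mean(coCounts(simulateBF(p$spec, p$precursor, p$patterning, 1,
                                 2000, seed = 32)))
  m2 <- mean(coCounts(simulateBF(p$spec, p$precursor, ptHi, 1,
                                 2000, seed = 32)))
  expect_lt(m2, m1)
})

test_that("two-round patterning restricts final COs to the intermediate array", {
  p <- bfPresets("yeastXV")
  tr <- twoRoundSimulate(p$spec, p$precursor, p$patterning, p$patterning,
                         1, 500, seed = 33)
  expect_true(all(mapply(function(f, i) all(f %in% i),
                         coPositions(tr$final),
                         coPositions(tr$intermediate))))
  # degenerate round 2 (huge Smax, vanishing L) returns round 1 unchanged
  pt2 <- patterningParams(Smax = 1e9, L = 1e-9, A = 1, cL = 1, cR = 1)
  tr2 <- twoRoundSimulate(p$spec, p$precursor, p$patterning, pt2,
                          1, 300, seed = 34)
  expect_identical(coPositions(tr2$final), coPositions(tr2$intermediate))
  # a bivalent with an empty round 1 has an empty round 2
  none <- precursorParams(0, E = 0, B = 1)
  tr0 <- twoRoundSimulate(p$spec, none, p$patterning, p$patterning,
                          1, 5, seed = 35)
  expect_true(all(coCounts(tr0$final) == 0))
})

test_that("two-round patterning strengthens short-range interference", {
  p <- bfPresets("yeastXV")
  tr <- twoRoundSimulate(p$spec, p$precursor, p$patterning, p$patterning,
                         1, 2000, seed = 9)
  one <- simulateBF(p$spec, p$precursor, p$patterning, 1, 2000, seed = 9)
  cTwo <- suppressWarnings(cocCurve(computeCoC(tr$final, nIntervals = 16)))
  cOne <- suppressWarnings(cocCurve(computeCoC(one, nIntervals = 16)))
  expect_lt(cTwo$coc[1], cOne$coc[1] + 0.05)
})

test_that("non-interfering CO scenarios add the expected fraction with provenance", {
  p <- bfPresets("yeastXV")
  sim <- simulateBF(p$spec, p$precursor, p$patterning, 1, 3000, seed = 36)

  same <- addNonInterfering(sim, scenario = 1, targetFraction = 0)
  expect_identical(coPositions(same), coPositions(sim))
  expect_true(all(unlist(same@provenance) == 0L))

  s1 <- addNonInterfering(sim, scenario = 1, targetFraction = 0.3,
                          seed = 37)
  addedFrac <- sum(unlist(s1@provenance)) / sum(coCounts(s1))
  expect_equal(addedFrac, 0.3, tolerance = 0.05)
  # scenario-1 additions come from leftover precursors
  added <- subsetByProvenance(s1, "added")
  ok <- mapply(function(a, l) all(a %in% l), coPositions(added),
               sim@metadata$leftoverPositions)
  expect_true(all(ok))

  expect_error(addNonInterfering(sim, scenario = 2, targetFraction = 0.3),
               "PrecursorParams")
  s2 <- addNonInterfering(sim, scenario = 2, targetFraction = 0.3,
                          scenario2Precursors = precursorParams(13, 0, 0),
                          seed = 38)
  expect_equal(sum(unlist(s2@provenance)) / sum(coCounts(s2)), 0.3,
               tolerance = 0.05)
})
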