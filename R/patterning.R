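# The designation engine: stress-driven sequential CO-designation with
# spreading, distance-decaying interference, end clamping and maturation.

#' Stress-relief multiplier along a bivalent
#'
#' Local effective stress at position `x` is `Smax * R(x)` where
#' `R(x) = max(0, 1 - sum_j exp(-|x - x_j|/L)
#'               - (1 - cL) exp(-x/L) - (1 - cR) exp(-(1 - x)/L))`,
#' summing the relief spreading from every prior designation (crack) `x_j`
#' and from the chromosome ends. A fully clamped end (`c = 1`) contributes
#' nothing; a free end (`c = 0`) acts as a pre-existing crack; a
#' hyper-clamped end (`c > 1`) raises `R` above 1 nearby. `R` is exactly 0
#' at any crack position.
#'
#' @param x positions in `[0, 1]` (vectorised).
#' @param cracks positions of prior designations.
#' @param params a [PatterningParams-class].
#' @return numeric vector of relief multipliers, `>= 0`.
#' @examples
#' pp <- patterningParams(Smax = 3.5, L = 0.25, A = 1)
#' reliefMultiplier(0.5, numeric(0), pp)        # 1: clamped, no cracks
#' reliefMultiplier(0.25, cracks = 0.5, pp)     # 1 - exp(-1)
#' @export
reliefMultiplier <- function(x, cracks, params) {
  stopifnot(is(params, "PatterningParams"))
  if (any(x < 0 | x > 1)) stop("positions must lie in [0, 1]")
  L <- params@L
  rel <- numeric(length(x))
  if (length(cracks))
    rel <- colSums(exp(-abs(outer(cracks, x, "-")) / L))
  rel <- rel + (1 - params@cL) * exp(-x / L) +
    (1 - params@cR) * exp(-(1 - x) / L)
  out <- pmax(0, 1 - rel)
  if (length(cracks))
    out[x %in% cracks] <- 0  # designation site supports no stress
  out
}

# Reactivity of a precursor of sensitivity s under law A
# (1 = s^2, 2 = s, 3 = 5/s, 4 = 1/s).
reactivity <- function(s, A) {
  if (any(s <= 0 | s >= 1)) stop("sensitivities must lie in (0, 1)")
  switch(A, s^2, s, 5 / s, 1 / s)
}

#' Deterministic scale of the designation threshold
#'
#' The reciprocal of the precursor's reactivity under law `A`: `1/s^2`,
#' `1/s`, `s/5` or `s` for `A = 1..4`. In the designation engine the actual
#' stochastic threshold of precursor `i` is this scale multiplied by a
#' unit-rate exponential deviate (see [designate()]).
#'
#' @param s sensitivities in (0, 1) (vectorised).
#' @param A reactivity law, one of 1, 2, 3, 4.
#' @return numeric vector of threshold scales, `> 0`.
#' @examples
#' designationThreshold(0.5, A = 2)  # 2
#' designationThreshold(0.5, A = 1)  # 4
#' designationThreshold(0.5, A = 3)  # 0.1
#' @export
designationThreshold <- function(s, A) {
  A <- as.integer(A)
  if (length(A) != 1L || !(A %in% 1:4)) stop("A must be one of 1, 2, 3, 4")
  1 / reactivity(s, A)
}

#' Sequential CO-designation along one bivalent
#'
#' The driving force `S` ramps from 0 to `Smax`. Precursor `i` designates at
#' the moment its local stress `S * R(x_i)` first reaches its threshold
#' `tau_i`; each designation instantaneously adds spreading relief, raising
#' the required force for every remaining precursor. This is implemented as
#' an event-driven loop: repeatedly compute `S_req(i) = tau_i / R(x_i)`,
#' designate the argmin if `S_req <= Smax` (ties broken by lower index),
#' update the relief field, and stop when the minimum exceeds `Smax`.
#' Because relief only accumulates, the loop is exactly equivalent to a
#' continuous ramp of `S`.
#'
#' Thresholds are stochastic: `tau_i = X_i / reactivity(s_i)` with `X_i` a
#' unit-rate exponential deviate, so a precursor's chance of escaping
#' designation up to force `S` is `exp(-reactivity * R * S)`. Pass
#' `thresholds` to override (e.g. for oracle comparisons).
#'
#' @param precursors a [PrecursorArray-class].
#' @param params a [PatterningParams-class].
#' @param thresholds optional numeric vector of designation thresholds,
#'   one per precursor; by default drawn as described above.
#' @return list with `designated` (positions in temporal designation
#'   order), `order` (indices into the array), `leftover` (indices of
#'   not-designated precursors), `sAtDesignation` (the force level at each
#'   designation, non-decreasing), and `thresholds`.
#' @export
designate <- function(precursors, params, thresholds = NULL) {
  stopifnot(is(precursors, "PrecursorArray"), is(params, "PatterningParams"))
  x <- precursors@positions
  n <- length(x)
  if (n == 0L)
    return(list(designated = numeric(0), order = integer(0),
                leftover = integer(0), sAtDesignation = numeric(0),
                thresholds = numeric(0)))
  if (is.null(thresholds))
    thresholds <- stats::rexp(n) *
      designationThreshold(precursors@sensitivities, params@A)
  if (length(thresholds) != n)
    stop("need one threshold per precursor")
  remaining <- seq_len(n)
  cracks <- numeric(0)
  ord <- integer(0)
  sAt <- numeric(0)
  repeat {
    if (!length(remaining)) break
    R <- reliefMultiplier(x[remaining], cracks, params)
    sreq <- ifelse(R > 0, thresholds[remaining] / R, Inf)
    m <- which.min(sreq)
    if (!is.finite(sreq[m]) || sreq[m] > params@Smax) break
    ord <- c(ord, remaining[m])
    sAt <- c(sAt, sreq[m])
    cracks <- c(cracks, x[remaining[m]])
    remaining <- remaining[-m]
  }
  list(designated = x[ord], order = ord, leftover = remaining,
       sAtDesignation = sAt, thresholds = thresholds)
}

#' Maturation thinning of designated COs
#'
#' Each designated CO survives to a detectable CO independently with
#' probability `M`.
#'
#' @param positions designated CO positions.
#' @param M maturation efficiency in `[0, 1]`.
#' @return the surviving positions.
#' @export
matureCOs <- function(positions, M) {
  M <- bfScalarProb(M, "M")
  if (M >= 1 || !length(positions)) return(positions)
  if (M <= 0) return(numeric(0))
  positions[stats::runif(length(positions)) < M]
}

#' Simulate CO patterns for many bivalents
#'
#' The full per-bivalent pipeline: draw a precursor array, run sequential
#' stress-driven designation, apply maturation thinning. Each bivalent uses
#' its own RNG substream derived from `seed` by a prefix-stable counter
#' scheme, so results for bivalent `i` do not depend on `nBivalents`.
#'
#' @param spec a [ChromosomeSpec-class].
#' @param precursor a [PrecursorParams-class].
#' @param patterning a [PatterningParams-class].
#' @param M maturation efficiency in `[0, 1]`.
#' @param nBivalents number of bivalents to simulate (the analyses in this
#'   package typically use 5000).
#' @param seed integer seed; `NULL` draws one from the session RNG.
#' @return a [BivalentSet-class]. Metadata records the seed, parameters,
#'   and per-bivalent leftover (not-designated) precursor positions and
#'   sensitivities, plus the designation order, for downstream use by
#'   [addNonInterfering()] and [twoRoundSimulate()].
#' @examples
#' p <- bfPresets("yeastXV")
#' sim <- simulateBF(p$spec, p$precursor, p$patterning, M = p$M,
#'                   nBivalents = 200, seed = 1)
#' mean(coCounts(sim))
#' @export
simulateBF <- function(spec, precursor, patterning, M = 1,
                       nBivalents = 5000, seed = NULL) {
  stopifnot(is(spec, "ChromosomeSpec"), is(precursor, "PrecursorParams"),
            is(patterning, "PatterningParams"))
  M <- bfScalarProb(M, "M")
  seed <- bfResolveSeed(seed)
  seeds <- bfSeedStream(seed, nBivalents)
  old <- bfSaveRNG(); on.exit(bfRestoreRNG(old))
  pos <- vector("list", nBivalents)
  leftoverPos <- vector("list", nBivalents)
  leftoverSens <- vector("list", nBivalents)
  designatedOrder <- vector("list", nBivalents)
  for (i in seq_len(nBivalents)) {
    set.seed(seeds[i])
    arr <- makePrecursorArray(spec, precursor)
    d <- designate(arr, patterning)
    pos[[i]] <- sort(matureCOs(d$designated, M))
    leftoverPos[[i]] <- arr@positions[d$leftover]
    leftoverSens[[i]] <- arr@sensitivities[d$leftover]
    designatedOrder[[i]] <- d$designated
  }
  new("BivalentSet", positions = pos, lengthsUm = spec@lengthUm,
      spec = spec, provenance = list(),
      metadata = list(seed = seed, M = M, precursor = precursor,
                      patterning = patterning,
                      leftoverPositions = leftoverPos,
                      leftoverSensitivities = leftoverSens,
                      designated = designatedOrder))
}

#' Two-round patterning simulation
#'
#' Models CO patterns that evolve in two stages: a first designation round
#' acts on the full precursor array; its designations (with freshly drawn
#' sensitivities) become the precursor array for a second round, whose
#' designations — after maturation thinning — are the final COs. A bivalent
#' whose first round yields no designation has an empty second round.
#'
#' @param spec a [ChromosomeSpec-class].
#' @param precursor a [PrecursorParams-class] for the round-1 array.
#' @param patterning1 round-1 [PatterningParams-class].
#' @param patterning2 round-2 [PatterningParams-class].
#' @param M maturation efficiency applied to round-2 designations.
#' @param nBivalents,seed as in [simulateBF()].
#' @return list with elements `final` and `intermediate`, both
#'   [BivalentSet-class] objects.
#' @export
twoRoundSimulate <- function(spec, precursor, patterning1, patterning2,
                             M = 1, nBivalents = 5000, seed = NULL) {
  stopifnot(is(spec, "ChromosomeSpec"), is(precursor, "PrecursorParams"))
  M <- bfScalarProb(M, "M")
  seed <- bfResolveSeed(seed)
  seeds <- bfSeedStream(seed, nBivalents)
  old <- bfSaveRNG(); on.exit(bfRestoreRNG(old))
  finalPos <- vector("list", nBivalents)
  midPos <- vector("list", nBivalents)
  for (i in seq_len(nBivalents)) {
    set.seed(seeds[i])
    arr <- makePrecursorArray(spec, precursor)
    d1 <- designate(arr, patterning1)
    mid <- sort(d1$designated)
    midPos[[i]] <- mid
    if (!length(mid)) {
      finalPos[[i]] <- numeric(0)
      next
    }
    arr2 <- new("PrecursorArray", positions = mid,
                sensitivities = assignSensitivities(length(mid)))
    d2 <- designate(arr2, patterning2)
    finalPos[[i]] <- sort(matureCOs(d2$designated, M))
  }
  meta <- list(seed = seed, M = M, precursor = precursor,
               patterning1 = patterning1, patterning2 = patterning2)
  list(final = new("BivalentSet", positions = finalPos,
                   lengthsUm = spec@lengthUm, spec = spec,
                   provenance = list(), metadata = meta),
       intermediate = new("BivalentSet", positions = midPos,
                          lengthsUm = spec@lengthUm, spec = spec,
                          provenance = list(), metadata = meta))
}

#' Add non-interfering COs to a simulated pattern
#'
#' Two scenarios for the origin of COs that escape the patterning process.
#' Scenario 1 selects uniformly at random from the precursors left over
#' (not designated) on each bivalent. Scenario 2 generates an independent
#' precursor array per bivalent from `scenario2Precursors` and selects
#' randomly from it. In both, the per-precursor selection probability is
#' set so that added COs comprise `targetFraction` of the combined total in
#' expectation: `p = f * T / ((1 - f) * A)` with `f` the target fraction,
#' `T` the mean patterned-CO count and `A` the mean available-precursor
#' count, clipped to 1.
#'
#' @param sim a [BivalentSet-class] produced by [simulateBF()] (its
#'   metadata must carry the leftover precursor positions).
#' @param scenario 1 or 2.
#' @param targetFraction desired fraction of added COs among all COs,
#'   in `[0, 1)`.
#' @param scenario2Precursors a [PrecursorParams-class] for scenario 2.
#' @param seed integer seed.
#' @return a [BivalentSet-class] with provenance flags (0 = patterned,
#'   1 = added).
#' @export
addNonInterfering <- function(sim, scenario = 1, targetFraction,
                              scenario2Precursors = NULL, seed = NULL) {
  stopifnot(is(sim, "BivalentSet"))
  if (targetFraction < 0 || targetFraction >= 1)
    stop("targetFraction must lie in [0, 1)")
  scenario <- as.integer(scenario)
  if (!scenario %in% c(1L, 2L)) stop("scenario must be 1 or 2")
  nBiv <- nBivalents(sim)
  if (targetFraction == 0) {
    prov <- lapply(sim@positions, function(p) integer(length(p)))
    out <- sim
    out@provenance <- prov
    return(out)
  }
  f <- targetFraction
  Tbar <- mean(coCounts(sim))
  seed <- bfResolveSeed(seed)
  seeds <- bfSeedStream(seed, nBiv)
  old <- bfSaveRNG(); on.exit(bfRestoreRNG(old))

  if (scenario == 1L) {
    leftover <- sim@metadata$leftoverPositions
    if (is.null(leftover))
      stop("scenario 1 needs leftover precursors in the simulation metadata")
    Abar <- mean(lengths(leftover))
    if (Abar <= 0) stop("no leftover precursors available on any bivalent")
    p <- min(1, f * Tbar / ((1 - f) * Abar))
    added <- vector("list", nBiv)
    for (i in seq_len(nBiv)) {
      set.seed(seeds[i])
      cand <- leftover[[i]]
      added[[i]] <- cand[stats::runif(length(cand)) < p]
    }
  } else {
    if (is.null(scenario2Precursors))
      stop("scenario 2 requires its own PrecursorParams")
    stopifnot(is(scenario2Precursors, "PrecursorParams"))
    Abar <- scenario2Precursors@N
    if (Abar <= 0) stop("scenario 2 precursor mean N must be positive")
    p <- min(1, f * Tbar / ((1 - f) * Abar))
    added <- vector("list", nBiv)
    for (i in seq_len(nBiv)) {
      set.seed(seeds[i])
      arr <- makePrecursorArray(sim@spec, scenario2Precursors)
      added[[i]] <- arr@positions[stats::runif(length(arr@positions)) < p]
    }
  }

  pos <- vector("list", nBiv)
  prov <- vector("list", nBiv)
  for (i in seq_len(nBiv)) {
    merged <- c(sim@positions[[i]], added[[i]])
    flags <- c(integer(length(sim@positions[[i]])),
               rep(1L, length(added[[i]])))
    o <- order(merged)
    pos[[i]] <- merged[o]
    prov[[i]] <- flags[o]
  }
  new("BivalentSet", positions = pos, lengthsUm = sim@lengthsUm,
      spec = sim@spec, provenance = prov,
      metadata = c(sim@metadata,
                   list(scenario = scenario, targetFraction = f,
                        selectionProb = p, addSeed = seed)))
}
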