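# Composite analyses: crossover homeostasis sweeps, obligatory-CO (zero-CO)
# sweeps, the homeostasis-strength ratio, grid-search fitting, and the
# one-call descriptor report.

simSummary <- function(sim, nIntervals = NULL) {
  k <- coCounts(sim)
  n <- length(k)
  zero <- mean(k == 0)
  out <- list(meanCO = mean(k),
              meanCOse = stats::sd(k) / sqrt(n),
              zeroFraction = zero,
              zeroSE = sqrt(zero * (1 - zero) / n))
  if (!is.null(nIntervals)) {
    out$lCoC <- lCoC(computeCoC(sim, nIntervals = nIntervals))
    g <- interCODistances(sim)
    out$nu <- if (length(g) >= 10) fitGamma(g)$shape else NA_real_
  }
  out
}

# Replace one named parameter inside the (precursor, patterning, M) block.
setParam <- function(precursor, patterning, M, name, value) {
  switch(name,
    N = precursor@N <- value,
    E = precursor@E <- value,
    B = precursor@B <- value,
    Smax = patterning@Smax <- value,
    L = patterning@L <- value,
    A = patterning@A <- as.integer(value),
    cL = patterning@cL <- value,
    cR = patterning@cR <- value,
    M = M <- value,
    stop("unknown parameter '", name, "'")
  )
  validObject(precursor); validObject(patterning)
  list(precursor = precursor, patterning = patterning, M = M)
}

#' Crossover homeostasis sweep over precursor number and interference distance
#'
#' Homeostasis — the buffering of CO numbers against changes in precursor
#' (DSB) numbers — is quantified by simulating every combination of `N` and
#' `L` and summarising mean COs per bivalent, COs per precursor, and the
#' zero-CO fraction. Columns `relN` and `relCO` express precursor and CO
#' levels relative to a reference `N` (default: the base parameter value),
#' the normalised view of homeostasis curves.
#'
#' @param spec a [ChromosomeSpec-class].
#' @param precursor base [PrecursorParams-class].
#' @param patterning base [PatterningParams-class].
#' @param M maturation efficiency.
#' @param NValues precursor numbers to sweep.
#' @param LValues interference distances (fractions) to sweep.
#' @param nBivalents bivalents per cell.
#' @param seed integer seed (shared across cells: common random numbers).
#' @param referenceN reference precursor number for the normalised view.
#' @return data.frame with one row per (N, L) combination.
#' @export
homeostasisSweep <- function(spec, precursor, patterning, M = 1,
                             NValues, LValues, nBivalents = 5000,
                             seed = NULL, referenceN = precursor@N) {
  seed <- bfResolveSeed(seed)
  grid <- expand.grid(N = NValues, L = LValues)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    pr <- precursor; pr@N <- grid$N[r]
    pt <- patterning; pt@L <- grid$L[r]
    s <- simSummary(simulateBF(spec, pr, pt, M, nBivalents, seed))
    data.frame(N = grid$N[r], L = grid$L[r],
               meanCO = s$meanCO, meanCOse = s$meanCOse,
               coPerPrecursor = s$meanCO / grid$N[r],
               zeroFraction = s$zeroFraction, zeroSE = s$zeroSE)
  })
  out <- do.call(rbind, rows)
  out$relN <- out$N / referenceN
  ref <- out[abs(out$N - referenceN) < 1e-9, c("L", "meanCO")]
  out$relCO <- NA_real_
  for (l in unique(out$L)) {
    r0 <- ref$meanCO[ref$L == l]
    if (length(r0) == 1 && r0 > 0)
      out$relCO[out$L == l] <- out$meanCO[out$L == l] / r0
  }
  attr(out, "seed") <- seed
  out
}

#' Zero-CO fraction sweep over one or two parameters
#'
#' Sweeps any of `N`, `E`, `B`, `Smax`, `L`, `A`, `cL`, `cR`, `M` and
#' reports the fraction of bivalents with zero COs (with Wilson 95%
#' intervals). For a two-parameter grid give two names and a data.frame of
#' value combinations.
#'
#' @param spec,precursor,patterning,M base parameters as in
#'   [homeostasisSweep()].
#' @param paramName parameter name, or two names for a 2-D grid.
#' @param values numeric vector, or a data.frame with one column per
#'   swept parameter.
#' @param nBivalents,seed as in [homeostasisSweep()].
#' @return data.frame with the swept values, `zeroFraction`, `zeroLower`,
#'   `zeroUpper`, `meanCO`.
#' @export
zeroCOSweep <- function(spec, precursor, patterning, M = 1,
                        paramName, values, nBivalents = 5000,
                        seed = NULL) {
  seed <- bfResolveSeed(seed)
  if (length(paramName) == 1L && !is.data.frame(values))
    values <- stats::setNames(data.frame(values), paramName)
  stopifnot(all(paramName %in% names(values)))
  rows <- lapply(seq_len(nrow(values)), function(r) {
    pp <- list(precursor = precursor, patterning = patterning, M = M)
    for (nm in paramName)
      pp <- setParam(pp$precursor, pp$patterning, pp$M, nm, values[r, nm])
    sim <- simulateBF(spec, pp$precursor, pp$patterning, pp$M,
                      nBivalents, seed)
    k <- coCounts(sim)
    ci <- wilsonInterval(sum(k == 0), length(k))
    cbind(values[r, , drop = FALSE],
          data.frame(zeroFraction = mean(k == 0),
                     zeroLower = ci[["lower"]], zeroUpper = ci[["upper"]],
                     meanCO = mean(k)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

#' Strength of crossover homeostasis
#'
#' The ratio between the empirical interference distance (L_CoC) and the
#' mean distance between adjacent precursors, both in micrometres. Higher
#' ratios mean more precursors fall inside the interference distance and
#' can be removed without affecting CO numbers, i.e. stronger homeostasis.
#'
#' @param lCoCUm interference distance L_CoC in micrometres.
#' @param meanInterPrecursorUm mean adjacent-precursor distance in
#'   micrometres.
#' @return list echoing the inputs with their `ratio`.
#' @examples
#' homeostasisStrength(0.3, 0.3)$ratio    # 1 (budding yeast)
#' homeostasisStrength(11, 0.888)$ratio   # about 12.4 (tomato)
#' @export
homeostasisStrength <- function(lCoCUm, meanInterPrecursorUm) {
  stopifnot(lCoCUm > 0, meanInterPrecursorUm > 0)
  list(lCoCUm = lCoCUm, meanInterPrecursorUm = meanInterPrecursorUm,
       ratio = lCoCUm / meanInterPrecursorUm)
}

# Total-variation distance between two CO-count histograms.
edTV <- function(h1, h2) {
  kmax <- max(h1$count, h2$count)
  f1 <- f2 <- numeric(kmax + 1)
  f1[h1$count + 1] <- h1$fraction
  f2[h2$count + 1] <- h2$fraction
  sum(abs(f1 - f2)) / 2
}

# RMSE between two averaged CoC curves on their common distance support.
cocRMSE <- function(c1, c2) {
  m <- merge(c1@curve[, c("distance", "coc")],
             c2@curve[, c("distance", "coc")], by = "distance")
  if (!nrow(m)) return(NA_real_)
  sqrt(mean((m$coc.x - m$coc.y)^2))
}

#' Grid-search fit of simulation parameters to an experimental data set
#'
#' Simulates every combination of the supplied parameter value lists
#' (common random numbers across combinations) and scores each against the
#' experimental data with four components: RMSE between averaged CoC curves
#' on the common distance support, absolute difference in mean COs per
#' bivalent, total-variation distance between event distributions, and
#' absolute difference in zero-CO fractions. Components are z-scaled across
#' the grid and combined as a weighted sum; the full ranked table is
#' returned, never only the top hit.
#'
#' @param expData experimental [BivalentSet-class] (50+ bivalents
#'   recommended).
#' @param spec a [ChromosomeSpec-class]; its length must match the
#'   experimental data's chromosome length.
#' @param precursor,patterning,M base parameters; grid entries override.
#' @param grid named list of value vectors for any of `N`, `E`, `B`,
#'   `Smax`, `L`, `A`, `cL`, `cR`, `M`.
#' @param weights weights for the four components
#'   (coc, meanCO, ed, zero).
#' @param nIntervals intervals for the CoC component.
#' @param nBivalents bivalents per simulated combination.
#' @param seed integer seed shared by all combinations.
#' @return data.frame with the grid, raw component scores (`cocRMSE`,
#'   `dMeanCO`, `edTV`, `dZero`), the z-scaled `composite`, and `rank`
#'   (1 = best), sorted best-first.
#' @export
fitScan <- function(expData, spec, precursor, patterning, M = 1,
                    grid, weights = c(coc = 1, meanCO = 1, ed = 1,
                                      zero = 1),
                    nIntervals = 20, nBivalents = 2000, seed = NULL) {
  stopifnot(is(expData, "BivalentSet"), length(grid) >= 1)
  if (abs(scLength(expData) - spec@lengthUm) > 1e-6 * spec@lengthUm)
    stop("chromosome lengths of data and spec do not match")
  seed <- bfResolveSeed(seed)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  expCoC <- computeCoC(expData, nIntervals = nIntervals)
  expED <- eventDistribution(expData)
  comp <- matrix(NA_real_, nrow(combos), 4,
                 dimnames = list(NULL, c("cocRMSE", "dMeanCO", "edTV",
                                         "dZero")))
  for (r in seq_len(nrow(combos))) {
    pp <- list(precursor = precursor, patterning = patterning, M = M)
    for (nm in names(combos))
      pp <- setParam(pp$precursor, pp$patterning, pp$M, nm, combos[r, nm])
    sim <- simulateBF(spec, pp$precursor, pp$patterning, pp$M,
                      nBivalents, seed)
    simCoC <- computeCoC(sim, nIntervals = nIntervals)
    simED <- eventDistribution(sim)
    comp[r, ] <- c(cocRMSE(expCoC, simCoC),
                   abs(expED$mean - simED$mean),
                   edTV(expED$histogram, simED$histogram),
                   abs(expED$zeroFraction - simED$zeroFraction))
  }
  z <- apply(comp, 2, function(v) {
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(numeric(length(v)))
    (v - mean(v, na.rm = TRUE)) / s
  })
  w <- weights[c("coc", "meanCO", "ed", "zero")]
  composite <- as.numeric(z %*% w)
  out <- cbind(combos, as.data.frame(comp),
               data.frame(composite = composite))
  out$rank <- rank(out$composite, ties.method = "first")
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "weights") <- w
  attr(out, "seed") <- seed
  out
}

#' One-call descriptor report for a CO data set
#'
#' Computes the standard descriptor battery — CoC curve and L_CoC, event
#' distribution, inter-CO distances with gamma-shape fit, and the CO
#' position histogram — with numbers identical to calling the pieces
#' separately.
#'
#' @param data a [BivalentSet-class].
#' @param nIntervals,intervalUm CoC interval specification (see
#'   [computeCoC()]).
#' @param nBins bins for the position histogram.
#' @return list with `coc` ([CoCCurve-class]), `lCoC` and `lCoCUm`, `ed`,
#'   `gamma` (or `NULL` with < 10 gaps), `histogram`, `meanInterCOUm`.
#' @export
analyzeDataset <- function(data, nIntervals = NULL, intervalUm = NULL,
                           nBins = 20) {
  stopifnot(is(data, "BivalentSet"))
  if (nBivalents(data) == 0L) stop("empty data set")
  coc <- computeCoC(data, nIntervals = nIntervals, intervalUm = intervalUm)
  gaps <- interCODistances(data)
  gapsUm <- interCODistances(data, unit = "um")
  list(coc = coc,
       lCoC = lCoC(coc),
       lCoCUm = lCoC(coc, unit = "um"),
       ed = eventDistribution(data),
       gamma = if (length(gaps) >= 10) fitGamma(gaps) else NULL,
       histogram = positionHistogram(data, nBins = nBins),
       meanInterCOUm = if (length(gapsUm)) mean(gapsUm) else NA_real_)
}
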