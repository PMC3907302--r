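#' Construct a ChromosomeSpec
#'
#' @param lengthUm physical SC length of the chromosome in micrometres.
#' @param density relative precursor density over equal-width bins
#'   (non-negative, at least one positive). Default: uniform.
#' @return a [ChromosomeSpec-class].
#' @examples
#' chromosomeSpec(3.2)                      # yeast chromosome XV scale
#' chromosomeSpec(94, density = c(1, 1, 0, 1, 1))  # central precursor gap
#' @export
chromosomeSpec <- function(lengthUm, density = 1) {
  new("ChromosomeSpec", lengthUm = as.numeric(lengthUm),
      density = as.numeric(density))
}

#' Construct PrecursorParams
#'
#' @param N mean precursors per bivalent.
#' @param E evenness of spacing in `[0, 1]` (0 random, 1 even).
#' @param B among-nucleus constancy in `[0, 1]` (0 Poisson, 1 constant).
#' @return a [PrecursorParams-class].
#' @export
precursorParams <- function(N, E = 0, B = 1) {
  new("PrecursorParams", N = as.numeric(N), E = as.numeric(E),
      B = as.numeric(B))
}

#' Construct PatterningParams
#'
#' The interference distance may be given either as a fraction of chromosome
#' length (`L`) or in micrometres (`LUm`, converted using `spec`).
#'
#' @param Smax maximum designation driving force.
#' @param L interference distance as a fraction of chromosome length.
#' @param LUm interference distance in micrometres (requires `spec`).
#' @param A reactivity law (1 = s^2, 2 = s, 3 = 5/s, 4 = 1/s).
#' @param cL,cR left/right end-clamping coefficients.
#' @param spec a [ChromosomeSpec-class], needed only with `LUm`.
#' @return a [PatterningParams-class].
#' @examples
#' patterningParams(Smax = 3.5, L = 0.1, A = 1, cL = 0.85, cR = 0.85)
#' patterningParams(Smax = 3.5, LUm = 0.32, spec = chromosomeSpec(3.2))
#' @export
patterningParams <- function(Smax, L = NULL, LUm = NULL, A = 1,
                             cL = 1, cR = 1, spec = NULL) {
  if (is.null(L)) {
    if (is.null(LUm) || is.null(spec))
      stop("supply L (fraction) or LUm together with a ChromosomeSpec")
    L <- LUm / spec@lengthUm
  }
  new("PatterningParams", Smax = as.numeric(Smax), L = as.numeric(L),
      A = as.integer(A), cL = as.numeric(cL), cR = as.numeric(cR))
}

#' Best-fit parameter constellations for the analysed organisms
#'
#' Returns the curated best-fit simulation parameter sets for the
#' experimental data sets analysed with this model: budding yeast
#' chromosomes III, XV, IV and XIV (BR background), the grasshopper
#' (*Chorthippus brunneus*) L3 bivalent, the *Drosophila melanogaster* X
#' chromosome, and the two tomato SC-length groups. Each entry holds the
#' chromosome description, precursor parameters, patterning parameters and
#' maturation efficiency, ready for [simulateBF()].
#'
#' The grasshopper entry includes the centromeric precursor "black hole":
#' relative density ramps linearly to zero across the mid-chromosome bins,
#' emulating the paucity of DSBs in centromeric heterochromatin.
#'
#' For the Drosophila X chromosome the interference distance is stored as
#' the fraction 0.2 of the 15 um SC; `drosophilaX$LAlt` records the
#' alternative fraction 0.4 (= 6 um, the chromosome's measured interference
#' distance) for sensitivity analysis. The two values cannot both be right;
#' the zero-CO predictions are insensitive to the choice.
#'
#' @param name optional preset name; with no argument, all presets.
#' @return a named list (or one element) with components `spec`,
#'   `precursor`, `patterning`, `M`, and documentation fields `meanCO`,
#'   `zeroCO`, `lCoCUm` recording the experimental descriptor values the
#'   fits reproduce.
#' @examples
#' names(bfPresets())
#' bfPresets("yeastXV")$patterning
#' @export
bfPresets <- function(name = NULL) {
  yeast <- function(lengthUm, Lfrac, N) {
    list(spec = chromosomeSpec(lengthUm),
         precursor = precursorParams(N = N, E = 0.6, B = 1),
         patterning = patterningParams(Smax = 3.5, L = Lfrac, A = 1,
                                       cL = 0.85, cR = 0.85),
         M = 1)
  }
  p <- list(
    yeastIII = c(yeast(1.2, 0.25, 6),
                 list(meanCO = 1.8, zeroCO = 0.01, lCoCUm = 0.3)),
    yeastXV = c(yeast(3.2, 0.1, 13),
                list(meanCO = 4.7, zeroCO = 0, lCoCUm = 0.3)),
    yeastIV = c(yeast(4.8, 0.075, 19),
                list(meanCO = 6.8, zeroCO = 0, lCoCUm = 0.3)),
    yeastXIV = c(yeast(2.1, 0.15, 11),
                 list(meanCO = 3.7, zeroCO = 0, lCoCUm = 0.3)),
    grasshopperL3 = list(
      spec = chromosomeSpec(94, density = grasshopperDensity()),
      precursor = precursorParams(N = 14, E = 0, B = 1),
      patterning = patterningParams(Smax = 2.3, L = 0.3, A = 2,
                                    cL = 1.1, cR = 0.96),
      M = 1, meanCO = 2.2, zeroCO = 0, lCoCUm = 28),
    drosophilaX = list(
      spec = chromosomeSpec(15),
      precursor = precursorParams(N = 6, E = 0.4, B = 0.5),
      patterning = patterningParams(Smax = 2.8, L = 0.2, A = 1,
                                    cL = 0.65, cR = 0.5),
      M = 1, LAlt = 0.4, meanCO = 1.44, zeroCO = 0.05, lCoCUm = 6),
    tomatoLong = list(
      spec = chromosomeSpec(22),
      precursor = precursorParams(N = 25, E = 0.6, B = 1),
      patterning = patterningParams(Smax = 1.05, L = 0.65, A = 3,
                                    cL = 1.7, cR = 1.1),
      M = 1, meanCO = 1.4, zeroCO = 0, lCoCUm = 11),
    tomatoShort = list(
      spec = chromosomeSpec(17),
      precursor = precursorParams(N = 20, E = 0.6, B = 1),
      patterning = patterningParams(Smax = 1.05, L = 0.8, A = 3,
                                    cL = 1.7, cR = 1.1),
      M = 1, meanCO = 1.2, zeroCO = 0, lCoCUm = 11)
  )
  if (is.null(name)) return(p)
  if (!name %in% names(p))
    stop("unknown preset '", name, "'; available: ",
         paste(names(p), collapse = ", "))
  p[[name]]
}

#' Centromeric "black hole" density profile
#'
#' A 17-bin relative precursor density profile in which density ramps
#' linearly from 1 to 0 into a central dead zone and back, emulating the
#' paucity of recombination precursors in centromeric heterochromatin of
#' the grasshopper L3 bivalent. The exact ramp shape is a package choice;
#' only "density decreases to zero over a central region" is constrained.
#'
#' @param nBins number of equal-width bins (default 17, matching the
#'   interval count used for the grasshopper CoC analysis).
#' @param hole fractional interval `c(start, end)` of the zero-density core.
#' @param rampBins number of bins over which density ramps to zero on each
#'   side of the core.
#' @return numeric vector of relative densities.
#' @export
grasshopperDensity <- function(nBins = 17, hole = c(0.45, 0.55),
                               rampBins = 2) {
  lo <- (seq_len(nBins) - 1) / nBins
  hi <- seq_len(nBins) / nBins
  mids <- (lo + hi) / 2
  d <- rep(1, nBins)
  # any bin touching the hole is fully dead, so the core carries no mass
  dead <- hi > hole[1] & lo < hole[2]
  d[dead] <- 0
  ramp <- rampBins / nBins
  deadLo <- min(lo[dead]); deadHi <- max(hi[dead])
  inLeft <- !dead & mids > deadLo - ramp & mids < deadLo
  inRight <- !dead & mids > deadHi & mids < deadHi + ramp
  d[inLeft] <- (deadLo - mids[inLeft]) / ramp
  d[inRight] <- (mids[inRight] - deadHi) / ramp
  d
}
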