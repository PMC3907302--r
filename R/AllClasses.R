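#' @import methods
NULL

#' ChromosomeSpec: physical description of one bivalent
#'
#' Holds the synaptonemal-complex (SC) length of the chromosome in
#' micrometres and a piecewise-constant relative precursor density profile
#' over equal-width bins. All internal coordinates are fractions of total
#' length in `[0, 1]`; micrometres appear only at input/output boundaries.
#'
#' @slot lengthUm physical SC length in micrometres (single positive value).
#' @slot density non-negative relative precursor density, one value per
#'   equal-width bin; at least one bin must be positive. A single value means
#'   uniform density.
#'
#' @seealso [chromosomeSpec()]
#' @export
setClass("ChromosomeSpec",
  representation(lengthUm = "numeric", density = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@lengthUm) != 1L || !is.finite(object@lengthUm) ||
        object@lengthUm <= 0)
      msg <- c(msg, "lengthUm must be a single positive number")
    if (length(object@density) < 1L || any(!is.finite(object@density)) ||
        any(object@density < 0) || all(object@density == 0))
      msg <- c(msg, "density bins must be non-negative with at least one > 0")
    if (length(msg)) msg else TRUE
  }
)

#' PrecursorParams: the precursor-array parameter block
#'
#' @slot N mean number of precursor interactions per bivalent (>= 0).
#' @slot E evenness of precursor spacing along the bivalent: 0 = random,
#'   1 = perfectly even.
#' @slot B constancy of precursor number among nuclei: 0 = Poisson,
#'   1 = constant.
#'
#' @seealso [precursorParams()]
#' @export
setClass("PrecursorParams",
  representation(N = "numeric", E = "numeric", B = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@N) != 1L || !is.finite(object@N) || object@N < 0)
      msg <- c(msg, "N must be a single number >= 0")
    if (length(object@E) != 1L || !is.finite(object@E) ||
        object@E < 0 || object@E > 1)
      msg <- c(msg, "E must lie in [0, 1]")
    if (length(object@B) != 1L || !is.finite(object@B) ||
        object@B < 0 || object@B > 1)
      msg <- c(msg, "B must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' PatterningParams: the designation-engine parameter block
#'
#' @slot Smax maximum designation driving force reached during the ramp.
#' @slot L interference distance as a fraction of chromosome length (the
#'   exponential decay constant of the spreading relief).
#' @slot A reactivity law relating precursor sensitivity `s` to designation
#'   reactivity: 1 = s^2, 2 = s, 3 = 5/s, 4 = 1/s.
#' @slot cL,cR end-clamping coefficients (>= 0). 1 = fully clamped (no end
#'   effect); 0 = free end, which behaves as a pre-existing designation;
#'   values > 1 model hyper-clamped ends that locally raise stress.
#'
#' @seealso [patterningParams()]
#' @export
setClass("PatterningParams",
  representation(Smax = "numeric", L = "numeric", A = "integer",
                 cL = "numeric", cR = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@Smax) != 1L || !is.finite(object@Smax) ||
        object@Smax <= 0)
      msg <- c(msg, "Smax must be a single positive number")
    if (length(object@L) != 1L || !is.finite(object@L) || object@L <= 0)
      msg <- c(msg, "L must be a single positive number")
    if (length(object@A) != 1L || !(object@A %in% 1:4))
      msg <- c(msg, "A must be one of 1, 2, 3, 4")
    if (length(object@cL) != 1L || !is.finite(object@cL) || object@cL < 0)
      msg <- c(msg, "cL must be >= 0")
    if (length(object@cR) != 1L || !is.finite(object@cR) || object@cR < 0)
      msg <- c(msg, "cR must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' PrecursorArray: one bivalent's precursor interactions
#'
#' @slot positions sorted positions as fractions of chromosome length.
#' @slot sensitivities per-precursor sensitivity `s` in the open interval
#'   (0, 1).
#'
#' @seealso [makePrecursorArray()]
#' @export
setClass("PrecursorArray",
  representation(positions = "numeric", sensitivities = "numeric"),
  validity = function(object) {
    msg <- character(0)
    p <- object@positions; s <- object@sensitivities
    if (length(p) != length(s))
      msg <- c(msg, "positions and sensitivities must have equal length")
    if (length(p) && (any(!is.finite(p)) || any(p < 0) || any(p > 1)))
      msg <- c(msg, "positions must lie in [0, 1]")
    if (length(p) > 1 && is.unsorted(p))
      msg <- c(msg, "positions must be sorted ascending")
    if (length(s) && (any(!is.finite(s)) || any(s <= 0) || any(s >= 1)))
      msg <- c(msg, "sensitivities must lie in the open interval (0, 1)")
    if (length(msg)) msg else TRUE
  }
)

#' BivalentSet: crossover positions along many bivalents
#'
#' The universal CO-pattern container shared by simulated and experimental
#' data: one sorted vector of CO positions (fractions of chromosome length)
#' per bivalent, plus the chromosome description and, where available,
#' per-bivalent physical lengths and provenance flags distinguishing
#' patterned (interfering) from added (non-interfering) COs.
#'
#' @slot positions list of sorted numeric vectors, one per bivalent, with
#'   CO positions as fractions in `[0, 1]`.
#' @slot lengthsUm per-bivalent physical length in micrometres (length 1,
#'   recycled, or one per bivalent).
#' @slot spec the [ChromosomeSpec-class] the data refer to.
#' @slot provenance optional list of integer vectors parallel to
#'   `positions`: 0 = patterned CO, 1 = added non-interfering CO.
#' @slot metadata free-form list (simulation parameters, seed, per-bivalent
#'   leftover precursors, ...).
#'
#' @seealso [simulateBF()], [readBivalentTable()]
#' @export
setClass("BivalentSet",
  representation(positions = "list", lengthsUm = "numeric",
                 spec = "ChromosomeSpec", provenance = "list",
                 metadata = "list"),
  validity = function(object) {
    msg <- character(0)
    ok <- vapply(object@positions, function(p) {
      is.numeric(p) && (!length(p) ||
        (all(is.finite(p)) && all(p >= 0) && all(p <= 1) && !is.unsorted(p)))
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "each bivalent's positions must be sorted fractions in [0, 1]")
    nl <- length(object@lengthsUm)
    if (!(nl == 1L || nl == length(object@positions)))
      msg <- c(msg, "lengthsUm must have length 1 or one value per bivalent")
    if (any(!is.finite(object@lengthsUm)) || any(object@lengthsUm <= 0))
      msg <- c(msg, "lengthsUm must be positive")
    if (length(object@provenance) &&
        length(object@provenance) != length(object@positions))
      msg <- c(msg, "provenance must be empty or parallel to positions")
    if (length(msg)) msg else TRUE
  }
)

#' CoCCurve: coefficient-of-coincidence analysis of a BivalentSet
#'
#' @slot pairs data.frame with one row per interval pair: interval indices
#'   `i`, `j`, centre-to-centre `distance` (fraction of length), observed and
#'   expected double-CO frequencies, and `coc` = observed/expected.
#' @slot curve averaged curve: one row per realised inter-interval distance
#'   with columns `distance` (fraction), `distanceUm`, mean `coc`, `nPairs`.
#' @slot intervalSize interval width as a fraction of chromosome length.
#' @slot nIntervals number of equal-width intervals.
#' @slot lengthUm chromosome length used for micron conversion.
#'
#' @seealso [computeCoC()], [lCoC()]
#' @export
setClass("CoCCurve",
  representation(pairs = "data.frame", curve = "data.frame",
                 intervalSize = "numeric", nIntervals = "integer",
                 lengthUm = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (object@nIntervals < 2L)
      msg <- c(msg, "a CoC analysis needs at least 2 intervals")
    if (nrow(object@pairs) && any(object@pairs$coc < 0, na.rm = TRUE))
      msg <- c(msg, "CoC values must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "ChromosomeSpec", function(object) {
  cat(sprintf("ChromosomeSpec: %.3g um SC length, %d density bin(s)\n",
              object@lengthUm, length(object@density)))
})

setMethod("show", "PrecursorParams", function(object) {
  cat(sprintf("PrecursorParams: N = %.3g, E = %.3g, B = %.3g\n",
              object@N, object@E, object@B))
})

setMethod("show", "PatterningParams", function(object) {
  cat(sprintf(
    "PatterningParams: Smax = %.3g, L = %.3g (fraction), A = %d, cL/cR = %.3g/%.3g\n",
    object@Smax, object@L, object@A, object@cL, object@cR))
})

setMethod("show", "PrecursorArray", function(object) {
  cat(sprintf("PrecursorArray with %d precursor(s)\n",
              length(object@positions)))
  if (length(object@positions)) {
    cat("  positions:    ",
        paste(sprintf("%.3f", utils::head(object@positions, 8)),
              collapse = " "),
        if (length(object@positions) > 8) "...\n" else "\n")
  }
})

setMethod("show", "BivalentSet", function(object) {
  k <- lengths(object@positions)
  cat(sprintf("BivalentSet: %d bivalents, mean %.3g CO/bivalent, %.3g um\n",
              length(object@positions), mean(k), mean(object@lengthsUm)))
  if (length(object@provenance))
    cat(sprintf("  provenance flags present (%.1f%% added COs)\n",
                100 * sum(unlist(object@provenance)) / max(1, sum(k))))
})

setMethod("show", "CoCCurve", function(object) {
  cat(sprintf(
    "CoCCurve: %d intervals of %.3g (fraction) = %.3g um; %d pairs\n",
    object@nIntervals, object@intervalSize,
    object@intervalSize * object@lengthUm, nrow(object@pairs)))
  lc <- lCoC(object)
  if (is.na(lc)) cat("  L_CoC: undefined (curve never rises through 0.5)\n")
  else cat(sprintf("  L_CoC = %.3g (fraction) = %.3g um\n",
                   lc, lc * object@lengthUm))
})
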