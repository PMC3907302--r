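# Precursor-array generation: how many precursors per bivalent, where they
# sit along the chromosome, and how sensitive each is to the designation
# driving force.

# Calibration table mapping evenness E to the even-grid mixing weight w used
# by placePrecursors(). Generated once by data-raw/evenness-calibration.R:
# w at E = 0.6 and E = 0.7 is tuned by bisection so that the gamma shape
# fitted to pooled inter-precursor gaps (13 precursors per bivalent, 5000
# bivalents) reproduces the anchor values nu = 2.4 and nu = 4.2; E = 0 is
# pure sorted-uniform (nu = 1) and E = 1 the exact even grid. Intermediate
# E interpolates linearly, which is monotone by construction.
.evennessTable <- list(
  E = c(0, 0.6, 0.7, 1),
  w = c(0, 0.22695, 0.39840, 1)
)

evennessWeight <- function(E) {
  stats::approx(.evennessTable$E, .evennessTable$w, xout = E,
                rule = 2, ties = "ordered")$y
}

#' Draw the number of precursors for one bivalent
#'
#' Precursor counts among nuclei follow a binomial family indexed by the
#' constancy parameter `B`: `Binomial(round(N/B), p = B)` for `B > 0`, so
#' that `B = 1` gives a constant count `round(N)` and `B -> 0` approaches
#' the Poisson(`N`) limit, which is used exactly at `B = 0`. The mean is
#' `N` whenever `N/B` is an integer.
#'
#' @param params a [PrecursorParams-class].
#' @return a single non-negative integer count.
#' @examples
#' set.seed(1)
#' samplePrecursorCount(precursorParams(N = 6, B = 1))   # always 6
#' samplePrecursorCount(precursorParams(N = 6, B = 0))   # Poisson(6)
#' @export
samplePrecursorCount <- function(params) {
  stopifnot(is(params, "PrecursorParams"))
  N <- params@N
  if (N <= 0) return(0L)
  if (params@B == 0) return(stats::rpois(1L, N))
  trials <- round(N / params@B)
  if (trials < 1) return(0L)
  stats::rbinom(1L, trials, params@B)
}

#' Place precursor positions along one bivalent
#'
#' Positions are generated in a "mass" coordinate as the per-bivalent
#' mixture `(1 - w) * sorted-uniform + w * even-grid`, where the even grid
#' is `g_i = (i - 0.5)/n` and the weight `w` is a fixed monotone calibration
#' of the evenness parameter `E` (see the package vignette). The mass
#' coordinate is then warped through the inverse cumulative density
#' transform of the chromosome's precursor density profile, so a density
#' "black hole" produces a local paucity of precursors regardless of `E`.
#'
#' @param n number of precursors to place.
#' @param E evenness in `[0, 1]`.
#' @param spec a [ChromosomeSpec-class] supplying the density profile.
#' @return sorted numeric vector of `n` positions in `[0, 1]`.
#' @examples
#' placePrecursors(4, E = 1, chromosomeSpec(1))  # 0.125 0.375 0.625 0.875
#' @export
placePrecursors <- function(n, E, spec = chromosomeSpec(1)) {
  stopifnot(is(spec, "ChromosomeSpec"))
  n <- as.integer(n)
  if (n < 0) stop("n must be non-negative")
  if (n == 0L) return(numeric(0))
  w <- evennessWeight(E)
  grid <- (seq_len(n) - 0.5) / n
  u <- sort(stats::runif(n))
  p <- (1 - w) * u + w * grid
  warpByDensity(p, spec@density)
}

# Inverse-CDF warp from the uniform "mass" coordinate to the physical
# coordinate implied by a piecewise-constant density profile. Zero-density
# bins receive zero mass and therefore no precursors.
warpByDensity <- function(p, density) {
  K <- length(density)
  if (K == 1L) return(p)
  cum <- cumsum(density) / sum(density)
  stats::approx(x = c(0, cum), y = (0:K) / K, xout = p,
                ties = "ordered")$y
}

#' Draw precursor sensitivities
#'
#' Sensitivities are i.i.d. uniform on (0, 1), redrawn independently for
#' every bivalent.
#'
#' @param n number of precursors.
#' @return numeric vector of `n` sensitivities in (0, 1).
#' @export
assignSensitivities <- function(n) {
  n <- as.integer(n)
  if (n < 0) stop("n must be non-negative")
  if (n == 0L) return(numeric(0))
  s <- stats::runif(n)
  # guard the open-interval invariant against the (astronomically rare)
  # exact 0 draw
  pmin(pmax(s, .Machine$double.eps), 1 - .Machine$double.eps)
}

#' Generate one bivalent's precursor array
#'
#' Composes [samplePrecursorCount()], [placePrecursors()] and
#' [assignSensitivities()] under the current RNG state; deterministic given
#' a seed.
#'
#' @param spec a [ChromosomeSpec-class].
#' @param params a [PrecursorParams-class].
#' @return a [PrecursorArray-class].
#' @examples
#' set.seed(7)
#' makePrecursorArray(chromosomeSpec(3.2), precursorParams(13, E = 0.6))
#' @export
makePrecursorArray <- function(spec, params) {
  n <- samplePrecursorCount(params)
  pos <- placePrecursors(n, params@E, spec)
  new("PrecursorArray", positions = pos,
      sensitivities = assignSensitivities(n))
}

#' Pooled inter-precursor gaps from simulated arrays
#'
#' Generates `nBivalents` precursor arrays and pools the gaps between
#' adjacent precursors (interior gaps only, end margins excluded). Used to
#' characterise precursor spacing, e.g. by gamma-shape fitting with
#' [fitGamma()].
#'
#' @param spec a [ChromosomeSpec-class].
#' @param params a [PrecursorParams-class].
#' @param nBivalents number of bivalents to generate.
#' @param seed integer seed (optional).
#' @return numeric vector of gaps (fractions of chromosome length).
#' @export
precursorGaps <- function(spec, params, nBivalents = 5000, seed = NULL) {
  seed <- bfResolveSeed(seed)
  seeds <- bfSeedStream(seed, nBivalents)
  old <- bfSaveRNG(); on.exit(bfRestoreRNG(old))
  gaps <- vector("list", nBivalents)
  for (i in seq_len(nBivalents)) {
    set.seed(seeds[i])
    arr <- makePrecursorArray(spec, params)
    if (length(arr@positions) >= 2)
      gaps[[i]] <- diff(arr@positions)
  }
  unlist(gaps, use.names = FALSE)
}
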