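# Descriptors of CO patterns: CoC curves and L_CoC, event distributions,
# inter-CO distances with gamma-shape fitting, position histograms.

# Map positions (fractions) to 1-based interval indices; half-open bins,
# the last bin absorbs p = 1.
intervalIndex <- function(p, nIntervals) {
  pmin(floor(p * nIntervals) + 1L, nIntervals)
}

# n x K logical presence matrix: does bivalent b have >= 1 CO in interval k?
# CoC is a per-bivalent presence statistic: multiple COs of one bivalent in
# one interval count once.
presenceMatrix <- function(data, nIntervals) {
  n <- nBivalents(data)
  P <- matrix(FALSE, n, nIntervals)
  for (b in seq_len(n)) {
    p <- data@positions[[b]]
    if (length(p)) P[b, unique(intervalIndex(p, nIntervals))] <- TRUE
  }
  P
}

#' Coefficient of coincidence analysis
#'
#' Divides the chromosome into equal-width intervals, computes the
#' frequency of bivalents with a CO in each interval, and for every
#' interval pair compares the observed frequency of bivalents with COs in
#' both ("double COs") against the product of the single-interval
#' frequencies: `CoC = observed / expected`. CoC values from all pairs at
#' the same centre-to-centre distance are averaged into the curve.
#'
#' Pairs whose expected double frequency is zero are skipped. A warning is
#' issued if the interval width exceeds 1/4 of the mean distance between
#' adjacent COs (closely spaced doubles would be missed).
#'
#' @param data a [BivalentSet-class].
#' @param nIntervals number of equal intervals; alternatively give
#'   `intervalUm` and the count is `round(length/intervalUm)`.
#' @param intervalUm interval size in micrometres.
#' @return a [CoCCurve-class].
#' @examples
#' toy <- bivalentSet(list(c(0.25, 0.75), c(0.25, 0.75), 0.25, 0.75))
#' cocPairs(computeCoC(toy, nIntervals = 2))$coc  # 8/9 by hand enumeration
#' @export
computeCoC <- function(data, nIntervals = NULL, intervalUm = NULL) {
  stopifnot(is(data, "BivalentSet"))
  n <- nBivalents(data)
  if (n == 0L) stop("empty data set")
  lengthUm <- scLength(data)
  if (is.null(nIntervals)) {
    if (is.null(intervalUm))
      stop("supply nIntervals or intervalUm")
    if (intervalUm > lengthUm)
      stop("interval size exceeds chromosome length")
    nIntervals <- max(2L, as.integer(round(lengthUm / intervalUm)))
  }
  nIntervals <- as.integer(nIntervals)
  if (nIntervals < 2L) stop("need at least 2 intervals")
  size <- 1 / nIntervals

  gaps <- interCODistances(data, unit = "fraction")
  if (length(gaps) && size > mean(gaps) / 4)
    warning(sprintf(
      "interval width %.3g exceeds 1/4 of the mean inter-CO distance %.3g; CoC at short distances will be underestimated",
      size, mean(gaps)))

  P <- presenceMatrix(data, nIntervals)
  f <- colMeans(P)
  obs <- crossprod(P) / n  # K x K observed double frequencies
  idx <- which(upper.tri(obs), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  expd <- f[i] * f[j]
  keep <- expd > 0
  i <- i[keep]; j <- j[keep]; expd <- expd[keep]
  pairs <- data.frame(
    i = i, j = j,
    distance = (j - i) * size,
    observed = obs[cbind(i, j)],
    expected = expd,
    coc = obs[cbind(i, j)] / expd
  )
  pairs <- pairs[order(pairs$distance, pairs$i), , drop = FALSE]
  rownames(pairs) <- NULL
  if (nrow(pairs)) {
    agg <- stats::aggregate(coc ~ distance, data = pairs, FUN = mean)
    np <- stats::aggregate(coc ~ distance, data = pairs, FUN = length)
    curve <- data.frame(distance = agg$distance,
                        distanceUm = agg$distance * lengthUm,
                        coc = agg$coc, nPairs = np$coc)
  } else {
    curve <- data.frame(distance = numeric(0), distanceUm = numeric(0),
                        coc = numeric(0), nPairs = integer(0))
  }
  new("CoCCurve", pairs = pairs, curve = curve, intervalSize = size,
      nIntervals = nIntervals, lengthUm = lengthUm)
}

#' Interference distance from a CoC curve
#'
#' The inter-interval distance at which the averaged CoC curve first rises
#' through 0.5, found by linear interpolation between the two bracketing
#' points. Undefined (`NA`) when the curve never drops below 0.5, or never
#' comes back up.
#'
#' @param curve a [CoCCurve-class].
#' @param unit `"fraction"` (default) or `"um"`.
#' @return the crossing distance, or `NA_real_` if undefined.
#' @export
lCoC <- function(curve, unit = c("fraction", "um")) {
  stopifnot(is(curve, "CoCCurve"))
  unit <- match.arg(unit)
  cc <- curve@curve
  if (!nrow(cc)) return(NA_real_)
  v <- cc$coc
  d <- cc$distance
  if (v[1] >= 0.5) return(NA_real_)  # curve never below 0.5 at short range
  k <- which(v[-1] >= 0.5 & v[-length(v)] < 0.5)
  if (!length(k)) return(NA_real_)
  k <- k[1]
  x <- d[k] + (0.5 - v[k]) * (d[k + 1] - d[k]) / (v[k + 1] - v[k])
  if (unit == "um") x * curve@lengthUm else x
}

#' Event distribution of CO counts
#'
#' The fractions of bivalents exhibiting different numbers of COs, their
#' mean, and the zero-CO fraction with a Wilson 95% interval.
#'
#' @param data a [BivalentSet-class].
#' @return list with `histogram` (data.frame `count`, `fraction`), `mean`,
#'   `zeroFraction`, `zeroCI` (Wilson 95%), and `n`.
#' @export
eventDistribution <- function(data) {
  stopifnot(is(data, "BivalentSet"))
  k <- coCounts(data)
  n <- length(k)
  if (n == 0L) stop("empty data set")
  tab <- tabulate(k + 1L, nbins = max(k) + 1L)
  hist <- data.frame(count = 0:max(k), fraction = tab / n)
  zero <- mean(k == 0)
  list(histogram = hist, mean = mean(k), zeroFraction = zero,
       zeroCI = wilsonInterval(sum(k == 0), n), n = n)
}

#' Distances between adjacent COs
#'
#' Pooled over bivalents with at least two COs; within-bivalent order is
#' preserved.
#'
#' @param data a [BivalentSet-class].
#' @param unit `"fraction"` or `"um"`.
#' @return numeric vector of adjacent-CO gaps.
#' @export
interCODistances <- function(data, unit = c("fraction", "um")) {
  stopifnot(is(data, "BivalentSet"))
  unit <- match.arg(unit)
  lens <- bivalentLengths(data)
  out <- vector("list", nBivalents(data))
  for (b in seq_along(out)) {
    p <- data@positions[[b]]
    if (length(p) >= 2) {
      g <- diff(p)
      out[[b]] <- if (unit == "um") g * lens[b] else g
    }
  }
  unlist(out, use.names = FALSE)
}

#' Maximum-likelihood gamma fit of inter-event distances
#'
#' Two-parameter gamma fit; the shape is found by Newton iteration on the
#' profile likelihood equation `log(shape) - digamma(shape) = log(mean(d))
#' - mean(log(d))` to a tolerance of 1e-8. The shape parameter (often
#' called nu in interference analysis) is scale-invariant, so fraction or
#' micron units give the same value.
#'
#' @param distances numeric vector of positive distances (at least 10).
#' @return list with `shape`, `scale`, `n`, `logLik`.
#' @examples
#' set.seed(1)
#' fitGamma(rexp(1000))$shape  # about 1
#' @export
fitGamma <- function(distances) {
  d <- distances[is.finite(distances) & distances > 0]
  if (length(d) < 10)
    stop("gamma fit requires at least 10 positive distances")
  mbar <- mean(d)
  cc <- log(mbar) - mean(log(d))
  if (cc < 1e-12) {
    shape <- 1e8  # essentially constant gaps
  } else {
    k <- (3 - cc + sqrt((cc - 3)^2 + 24 * cc)) / (12 * cc)
    for (it in 1:200) {
      f <- log(k) - digamma(k) - cc
      fp <- 1 / k - trigamma(k)
      knew <- k - f / fp
      if (!is.finite(knew) || knew <= 0) knew <- k / 2
      if (abs(knew - k) < 1e-8 * max(1, k)) { k <- knew; break }
      k <- knew
    }
    shape <- k
  }
  scale <- mbar / shape
  list(shape = shape, scale = scale, n = length(d),
       logLik = sum(stats::dgamma(d, shape = shape, scale = scale,
                                  log = TRUE)))
}

#' CO position histogram
#'
#' Per-bin CO frequency (COs per bivalent per bin). With `coClass` the data
#' are restricted to bivalents with exactly that many COs, and with
#' `byRank = TRUE` frequencies are split by CO rank from the left end
#' (1st, 2nd, ...).
#'
#' @param data a [BivalentSet-class].
#' @param nBins number of equal bins.
#' @param byRank split by CO rank (requires `coClass`).
#' @param coClass restrict to bivalents with exactly this CO count.
#' @return data.frame with `bin`, `mid` (bin midpoint, fraction), `freq`,
#'   and `rank` when `byRank`.
#' @export
positionHistogram <- function(data, nBins = 20, byRank = FALSE,
                              coClass = NULL) {
  stopifnot(is(data, "BivalentSet"))
  nBins <- as.integer(nBins)
  pos <- data@positions
  if (!is.null(coClass))
    pos <- pos[lengths(pos) == coClass]
  n <- length(pos)
  if (n == 0L) stop("no bivalents selected")
  mids <- (seq_len(nBins) - 0.5) / nBins
  if (byRank) {
    if (is.null(coClass))
      stop("byRank requires coClass (a fixed CO count per bivalent)")
    out <- do.call(rbind, lapply(seq_len(coClass), function(r) {
      p <- vapply(pos, `[`, numeric(1), r)
      cnt <- tabulate(intervalIndex(p, nBins), nBins)
      data.frame(bin = seq_len(nBins), mid = mids, rank = r,
                 freq = cnt / n)
    }))
    rownames(out) <- NULL
    return(out)
  }
  cnt <- tabulate(intervalIndex(unlist(pos, use.names = FALSE), nBins),
                  nBins)
  data.frame(bin = seq_len(nBins), mid = mids, freq = cnt / n)
}

#' CoC restricted to interval pairs spanning a region
#'
#' Recomputes the averaged CoC curve using only interval pairs whose span
#' contains a given region (e.g. the centromere), for comparison with the
#' all-pairs curve: if interference is transmitted across the region, the
#' two curves coincide.
#'
#' @param data a [BivalentSet-class].
#' @param region `c(start, end)` in fractions of chromosome length, or
#'   `NULL` for no restriction.
#' @param nIntervals,intervalUm as in [computeCoC()].
#' @return a [CoCCurve-class] whose pairs all span `region`.
#' @export
cocSubsetSpanning <- function(data, region = NULL, nIntervals = NULL,
                              intervalUm = NULL) {
  full <- computeCoC(data, nIntervals = nIntervals,
                     intervalUm = intervalUm)
  if (is.null(region)) return(full)
  if (length(region) != 2L || region[1] > region[2] ||
      region[1] < 0 || region[2] > 1)
    stop("region must be c(start, end) within [0, 1]")
  size <- full@intervalSize
  pairs <- full@pairs
  keep <- (pairs$i - 1) * size <= region[1] & pairs$j * size >= region[2]
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs)) {
    agg <- stats::aggregate(coc ~ distance, data = pairs, FUN = mean)
    np <- stats::aggregate(coc ~ distance, data = pairs, FUN = length)
    curve <- data.frame(distance = agg$distance,
                        distanceUm = agg$distance * full@lengthUm,
                        coc = agg$coc, nPairs = np$coc)
  } else {
    curve <- data.frame(distance = numeric(0), distanceUm = numeric(0),
                        coc = numeric(0), nPairs = integer(0))
  }
  new("CoCCurve", pairs = pairs, curve = curve,
      intervalSize = full@intervalSize, nIntervals = full@nIntervals,
      lengthUm = full@lengthUm)
}
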