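#' Accessors for beamfilm classes
#'
#' Small accessor functions are preferred over direct slot access.
#'
#' @param x a beamfilm object.
#' @return `coPositions` returns the list of per-bivalent CO positions
#'   (fractions); `coCounts` the integer CO count per bivalent;
#'   `nBivalents` the number of bivalents; `scLength` the chromosome length
#'   in micrometres; `densityProfile` the relative precursor density bins;
#'   `cocPairs` and `cocCurve` the per-pair table and the averaged curve of
#'   a [CoCCurve-class]; `intervalWidth` the CoC interval width (fraction).
#' @name accessors
NULL

#' @rdname accessors
#' @export
coPositions <- function(x) {
  stopifnot(is(x, "BivalentSet"))
  x@positions
}

#' @rdname accessors
#' @export
coCounts <- function(x) {
  stopifnot(is(x, "BivalentSet"))
  lengths(x@positions)
}

#' @rdname accessors
#' @export
nBivalents <- function(x) {
  stopifnot(is(x, "BivalentSet"))
  length(x@positions)
}

#' @rdname accessors
#' @export
scLength <- function(x) {
  if (is(x, "BivalentSet")) return(x@spec@lengthUm)
  stopifnot(is(x, "ChromosomeSpec"))
  x@lengthUm
}

#' @rdname accessors
#' @export
bivalentLengths <- function(x) {
  stopifnot(is(x, "BivalentSet"))
  rep_len(x@lengthsUm, length(x@positions))
}

#' @rdname accessors
#' @export
densityProfile <- function(x) {
  if (is(x, "BivalentSet")) return(x@spec@density)
  stopifnot(is(x, "ChromosomeSpec"))
  x@density
}

#' @rdname accessors
#' @export
cocPairs <- function(x) {
  stopifnot(is(x, "CoCCurve"))
  x@pairs
}

#' @rdname accessors
#' @export
cocCurve <- function(x) {
  stopifnot(is(x, "CoCCurve"))
  x@curve
}

#' @rdname accessors
#' @export
intervalWidth <- function(x) {
  stopifnot(is(x, "CoCCurve"))
  x@intervalSize
}

#' Subset a BivalentSet by CO provenance
#'
#' After [addNonInterfering()], each CO carries a provenance flag
#' (0 = patterned/interfering, 1 = added/non-interfering). This extracts one
#' class of COs as a new [BivalentSet-class] with the same bivalents.
#'
#' @param x a [BivalentSet-class] with provenance flags.
#' @param which `"interfering"` or `"added"`.
#' @return a [BivalentSet-class].
#' @export
subsetByProvenance <- function(x, which = c("interfering", "added")) {
  which <- match.arg(which)
  stopifnot(is(x, "BivalentSet"))
  if (!length(x@provenance))
    stop("this BivalentSet carries no provenance flags")
  flag <- if (which == "added") 1L else 0L
  pos <- mapply(function(p, f) p[f == flag], x@positions, x@provenance,
                SIMPLIFY = FALSE)
  new("BivalentSet", positions = pos, lengthsUm = x@lengthsUm,
      spec = x@spec, provenance = list(),
      metadata = c(x@metadata, list(provenanceSubset = which)))
}
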