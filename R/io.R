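# File formats and fixtures. The exchange dialect is a tab-separated table
# with '#' comment headers: one row per bivalent with its SC length in um
# and its ordered CO positions in um from the labeled end, joined by ';'.

#' Construct a BivalentSet from position lists
#'
#' @param positions list of numeric vectors of CO positions as fractions of
#'   chromosome length (each sorted ascending), or a single vector for one
#'   bivalent per element convenience.
#' @param lengthsUm per-bivalent physical length in micrometres (length 1
#'   or one per bivalent).
#' @param spec optional [ChromosomeSpec-class]; defaults to a uniform
#'   chromosome of the mean length.
#' @return a [BivalentSet-class].
#' @examples
#' bivalentSet(list(c(0.2, 0.7), numeric(0), 0.5), lengthsUm = 3.2)
#' @export
bivalentSet <- function(positions, lengthsUm = 1, spec = NULL) {
  positions <- lapply(positions, function(p) sort(as.numeric(p)))
  if (is.null(spec)) spec <- chromosomeSpec(mean(lengthsUm))
  new("BivalentSet", positions = positions,
      lengthsUm = as.numeric(lengthsUm), spec = spec,
      provenance = list(), metadata = list())
}

#' Read a per-bivalent CO-position table
#'
#' Expects a tab-separated file with a mandatory header row
#' `bivalent_id  length_um  co_positions_um` and optional `#` comment
#' lines. CO positions are ordered, semicolon-separated micron coordinates
#' measured from the labeled chromosome end; an empty field is a legal
#' zero-CO bivalent. Positions are normalised to fractions of the row's
#' length.
#'
#' @param path file path.
#' @return a [BivalentSet-class]; per-row lengths are retained.
#' @export
readBivalentTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data rows in ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  need <- c("bivalent_id", "length_um", "co_positions_um")
  if (!all(need %in% header))
    stop("missing column(s): ",
         paste(setdiff(need, header), collapse = ", "))
  idx <- match(need, header)
  rows <- lines[-1]
  positions <- vector("list", length(rows))
  lens <- numeric(length(rows))
  for (r in seq_along(rows)) {
    fields <- strsplit(rows[[r]], "\t", fixed = TRUE)[[1]]
    # a zero-CO bivalent legally leaves the final field empty, which
    # strsplit() drops; pad trailing fields back
    if (length(fields) == length(header) - 1L) fields <- c(fields, "")
    if (length(fields) < max(idx))
      stop("row ", r, ": expected ", max(idx), " columns")
    len <- suppressWarnings(as.numeric(fields[idx[2]]))
    if (!is.finite(len) || len <= 0)
      stop("row ", r, ": length_um must be a positive number")
    posField <- trimws(fields[idx[3]])
    if (!nzchar(posField)) {
      pos <- numeric(0)
    } else {
      pos <- suppressWarnings(
        as.numeric(strsplit(posField, ";", fixed = TRUE)[[1]]))
      if (any(!is.finite(pos)))
        stop("row ", r, ": unparseable CO position")
      if (any(diff(pos) <= 0))
        stop("row ", r, ": CO positions must be strictly increasing")
      if (any(pos < 0) || any(pos > len))
        stop("row ", r, ": CO position outside [0, length_um]")
    }
    positions[[r]] <- pos / len
    lens[r] <- len
  }
  bivalentSet(positions, lengthsUm = lens)
}

#' Write a per-bivalent CO-position table
#'
#' Inverse of [readBivalentTable()] up to float formatting (6 significant
#' digits). Simulation parameters and the seed found in the object's
#' metadata are echoed as `#` header comments.
#'
#' @param data a [BivalentSet-class].
#' @param path output file path.
#' @param comments extra comment lines (without the leading `#`).
#' @return `path`, invisibly.
#' @export
writeBivalentTable <- function(data, path, comments = character()) {
  stopifnot(is(data, "BivalentSet"))
  lens <- bivalentLengths(data)
  meta <- data@metadata
  auto <- character(0)
  if (!is.null(meta$seed)) auto <- c(auto, paste("seed =", meta$seed))
  if (!is.null(meta$patterning)) {
    pt <- meta$patterning
    auto <- c(auto, sprintf("Smax = %g; L = %g; A = %d; cL = %g; cR = %g",
                            pt@Smax, pt@L, pt@A, pt@cL, pt@cR))
  }
  if (!is.null(meta$precursor)) {
    pr <- meta$precursor
    auto <- c(auto, sprintf("N = %g; E = %g; B = %g", pr@N, pr@E, pr@B))
  }
  if (!is.null(meta$M)) auto <- c(auto, paste("M =", meta$M))
  hdr <- c(paste("#", c(comments, auto)),
           "bivalent_id\tlength_um\tco_positions_um")
  body <- vapply(seq_along(data@positions), function(r) {
    um <- data@positions[[r]] * lens[r]
    paste(sprintf("b%d", r), format(signif(lens[r], 6)),
          paste(format(signif(um, 6), trim = TRUE), collapse = ";"),
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a flat key = value run configuration
#'
#' Lines of the form `key = value`; `#` starts a comment; repeated keys
#' accumulate into vectors (used for scan grids); values that parse as
#' numbers become numeric, and whitespace-separated multi-number values
#' become numeric vectors (e.g. density profiles).
#'
#' @param path file path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(strsplit(val, "\\s+")[[1]]))
    parsed <- if (any(is.na(num))) val else num
    cfg[[key]] <- if (is.null(cfg[[key]])) parsed else
      c(cfg[[key]], parsed)
  }
  cfg
}

# Build (spec, precursor, patterning, M, nBivalents, seed) from a config
# list; used by the command-line interface.
configToParams <- function(cfg) {
  need <- c("length_um", "N", "Smax", "L")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config missing required key(s): ", paste(miss, collapse = ", "))
  density <- if (!is.null(cfg$density)) cfg$density else 1
  spec <- chromosomeSpec(cfg$length_um[1], density = density)
  grab <- function(key, default) if (is.null(cfg[[key]])) default else
    cfg[[key]][1]
  list(spec = spec,
       precursor = precursorParams(N = cfg$N[1], E = grab("E", 0),
                                   B = grab("B", 1)),
       patterning = patterningParams(Smax = cfg$Smax[1], L = cfg$L[1],
                                     A = grab("A", 1),
                                     cL = grab("cL", 1),
                                     cR = grab("cR", 1)),
       M = grab("M", 1),
       nBivalents = as.integer(grab("n_bivalents", 5000)),
       seed = grab("seed", NULL),
       intervalUm = grab("interval_um", NA),
       nIntervals = grab("n_intervals", NA))
}

#' Generate the reference fixture files
#'
#' Writes four small per-bivalent tables used by the test suite and the
#' documentation:
#' \describe{
#'   \item{toy-coc.tsv}{the 4-bivalent hand-checkable CoC example
#'     (2 intervals; CoC = 8/9).}
#'   \item{yeastXV-like.tsv}{a simulated set at the yeast chromosome XV
#'     best-fit parameter values (synthetic, not experimental data).}
#'   \item{poisson-null.tsv}{a no-interference set: Poisson CO counts,
#'     i.i.d. uniform positions (CoC = 1 at all distances in expectation).}
#'   \item{grasshopper-like.tsv}{a simulated set at the grasshopper L3
#'     best-fit values including the centromeric density black hole
#'     (synthetic).}
#' }
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed.
#' @param nBivalents bivalents for the simulated fixtures.
#' @return named character vector of file paths, invisibly.
#' @export
makeFixtures <- function(outDir, seed = 1, nBivalents = 300) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(toy = file.path(outDir, "toy-coc.tsv"),
             yeast = file.path(outDir, "yeastXV-like.tsv"),
             poisson = file.path(outDir, "poisson-null.tsv"),
             grasshopper = file.path(outDir, "grasshopper-like.tsv"))

  toy <- bivalentSet(list(c(0.25, 0.75), c(0.25, 0.75), 0.25, 0.75),
                     lengthsUm = 1)
  writeBivalentTable(toy, paths["toy"],
                     comments = "4-bivalent CoC example, 2 intervals")

  p <- bfPresets("yeastXV")
  sim <- simulateBF(p$spec, p$precursor, p$patterning, M = p$M,
                    nBivalents = nBivalents, seed = seed)
  writeBivalentTable(sim, paths["yeast"],
                     comments = "synthetic: yeast chromosome XV best-fit parameters")

  old <- bfSaveRNG(); on.exit(bfRestoreRNG(old))
  set.seed(seed)
  pois <- bivalentSet(
    lapply(stats::rpois(nBivalents, 4), function(k) sort(stats::runif(k))),
    lengthsUm = 3.2)
  writeBivalentTable(pois, paths["poisson"],
                     comments = "synthetic: independent (Poisson) COs, no interference")

  g <- bfPresets("grasshopperL3")
  simg <- simulateBF(g$spec, g$precursor, g$patterning, M = g$M,
                     nBivalents = nBivalents, seed = seed + 1)
  writeBivalentTable(simg, paths["grasshopper"],
                     comments = "synthetic: grasshopper L3 best-fit parameters with centromeric black hole")

  invisible(paths)
}
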