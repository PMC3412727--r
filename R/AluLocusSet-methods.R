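#' Construct an AluLocusSet
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet] of
#'   locus sequences (element body + 3' flank, element sense). Lowercase
#'   input is normalized to uppercase.
#' @param ranges Optional [GenomicRanges::GRanges] parallel to `seqs`.
#' @param cellLines Optional list (or [IRanges::CharacterList]) of cell
#'   line labels per locus.
#'
#' @return An [AluLocusSet-class] object.
#' @examples
#' AluLocusSet(c(locus1 = "ACGTACGT"), cellLines = list("HeLa"))
#' @export
AluLocusSet <- function(seqs, ranges = NULL, cellLines = NULL) {
  if (is.character(seqs))
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  else
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  if (is.null(ranges))
    ranges <- GenomicRanges::GRanges()
  if (is.null(cellLines))
    cellLines <- replicate(length(seqs), character(0), simplify = FALSE)
  cellLines <- IRanges::CharacterList(cellLines)
  new("AluLocusSet", seqs = seqs, ranges = ranges, cellLines = cellLines)
}

#' @rdname AluLocusSet-class
#' @export
setMethod("lociIds", "AluLocusSet", function(x) names(x@seqs))

#' @rdname AluLocusSet-class
#' @export
setMethod("lociSeqs", "AluLocusSet", function(x) x@seqs)

#' @rdname AluLocusSet-class
#' @export
setMethod("lociRanges", "AluLocusSet", function(x) x@ranges)

#' @rdname AluLocusSet-class
#' @export
setMethod("cellLines", "AluLocusSet", function(x) x@cellLines)

#' @rdname AluLocusSet-class
#' @export
setMethod("length", "AluLocusSet", function(x) length(x@seqs))

#' @rdname AluLocusSet-class
#' @param i Index for subsetting.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "AluLocusSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i))
    i <- match(i, names(x@seqs))
  new("AluLocusSet",
      seqs = x@seqs[i],
      ranges = if (length(x@ranges)) x@ranges[i] else x@ranges,
      cellLines = x@cellLines[i])
})

setMethod("show", "AluLocusSet", function(object) {
  cat(sprintf("AluLocusSet with %d loci\n", length(object)))
  if (length(object)) {
    w <- Biostrings::width(object@seqs)
    cat(sprintf("  sequence widths: %d..%d\n", min(w), max(w)))
    cat(sprintf("  coordinates: %s\n",
                if (length(object@ranges)) "present" else "absent"))
    cl <- unique(unlist(object@cellLines))
    if (length(cl))
      cat(sprintf("  cell lines: %s\n", paste(cl, collapse = ", ")))
  }
})

#' Combine AluLocusSet objects
#'
#' @param x,... `AluLocusSet` objects to concatenate. Locus identifiers
#'   must remain unique after concatenation.
#' @return An `AluLocusSet`.
#' @export
setMethod("c", "AluLocusSet", function(x, ...) {
  sets <- c(list(x), list(...))
  rng <- lapply(sets, function(s) s@ranges)
  haveRanges <- vapply(rng, length, 1L) > 0L
  new("AluLocusSet",
      seqs = do.call(c, lapply(sets, function(s) s@seqs)),
      ranges = if (all(haveRanges)) do.call(c, rng) else GenomicRanges::GRanges(),
      cellLines = do.call(c, lapply(sets, function(s) s@cellLines)))
})

#' @rdname ConsensusLibrary-class
#' @param consensus Named character vector or DNAStringSet of consensus
#'   sequences.
#' @param ageClass Named character vector of age classes (`J`, `S`, `Y`,
#'   `Ya5`, `Yb8`, `other`); subfamilies without an entry default to
#'   `other`.
#' @export
ConsensusLibrary <- function(consensus, ageClass = character(0)) {
  if (is.character(consensus))
    consensus <- Biostrings::DNAStringSet(toupper(consensus))
  full <- setNames(rep("other", length(consensus)), names(consensus))
  full[names(ageClass)] <- ageClass
  new("ConsensusLibrary", consensus = consensus, ageClass = full)
}

#' @rdname ConsensusLibrary-class
#' @export
setMethod("consensusSeqs", "ConsensusLibrary", function(x) x@consensus)

#' @rdname ConsensusLibrary-class
#' @export
setMethod("ageClasses", "ConsensusLibrary", function(x) x@ageClass)

#' @rdname ConsensusLibrary-class
#' @export
setMethod("length", "ConsensusLibrary", function(x) length(x@consensus))

setMethod("show", "ConsensusLibrary", function(object) {
  cat(sprintf("ConsensusLibrary with %d subfamilies\n", length(object)))
  for (nm in names(object@consensus))
    cat(sprintf("  %-10s %4d bp  age class %s\n", nm,
                Biostrings::width(object@consensus[nm]),
                object@ageClass[[nm]]))
})

#' Thresholds for the dichotomous key
#'
#' @param divergenceBins Percent-divergence breakpoints (default `c(5, 10)`):
#'   below the first is the best bin, between them the middle bin, above
#'   the second the element is classified retrotranspositionally inactive.
#' @param aTailMin Minimum A-tail length (bases) for a pass; inclusive
#'   (default 20).
#' @param uniqueMax Maximum unique-region length (bases) for a pass;
#'   inclusive (default 20).
#' @param disruptionMax Maximum percent A-tail disruption for a pass;
#'   inclusive (default 10).
#' @return A [KeyConfig-class] object.
#' @examples
#' keyConfig()
#' @export
keyConfig <- function(divergenceBins = c(5, 10), aTailMin = 20,
                      uniqueMax = 20, disruptionMax = 10) {
  new("KeyConfig", divergenceBins = as.numeric(divergenceBins),
      aTailMin = as.numeric(aTailMin), uniqueMax = as.numeric(uniqueMax),
      disruptionMax = as.numeric(disruptionMax))
}

setMethod("show", "KeyConfig", function(object) {
  cat("Dichotomous key thresholds:\n")
  cat(sprintf("  divergence bins: <%g%%, %g-%g%%, >%g%% (inactive)\n",
              object@divergenceBins[1], object@divergenceBins[1],
              object@divergenceBins[2], object@divergenceBins[2]))
  cat(sprintf("  A-tail length  : >= %g bases\n", object@aTailMin))
  cat(sprintf("  unique length  : <= %g bases\n", object@uniqueMax))
  cat(sprintf("  tail disruption: <= %g%%\n", object@disruptionMax))
})

setMethod("show", "ScoreTables", function(object) {
  cat("ERP score tables (piecewise-linear R factors), floor =",
      format(object@floor), "\n")
  for (nm in c("divergence", "aTail", "unique", "disruption")) {
    tab <- slot(object, nm)
    cat(sprintf("  %-10s: %s\n", nm,
                paste(sprintf("(%g, %.3g)", tab$value, tab$R), collapse = " ")))
  }
})
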