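#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom stats setNames
#' @importFrom utils head
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom IRanges CharacterList
NULL

#' AluLocusSet: a set of candidate Alu loci
#'
#' Container for candidate Alu loci: the element-sense sequence of each
#' locus (element body plus downstream 3' flank), optional genomic
#' coordinates, and the set of cell lines (or datasets) in which each
#' locus was identified.
#'
#' @slot seqs A named [Biostrings::DNAStringSet] holding, for each locus,
#'   the element body followed by up to the configured window of 3'
#'   genomic flank, always in element-sense orientation (the poly-A tail
#'   and pol III terminator are downstream).
#' @slot ranges A [GenomicRanges::GRanges] of genomic coordinates
#'   (0 length when loci come from plain FASTA with no coordinates;
#'   otherwise parallel to `seqs`).
#' @slot cellLines An [IRanges::CharacterList] parallel to `seqs`: the
#'   cell lines each locus was retrieved from (may be empty).
#'
#' @seealso [loadLociFromFasta()], [loadLociFromBed()], [generateCohort()]
#' @export
setClass("AluLocusSet",
  representation(
    seqs = "DNAStringSet",
    ranges = "GRanges",
    cellLines = "CharacterList"
  )
)

setValidity("AluLocusSet", function(object) {
  msg <- character(0)
  ids <- names(object@seqs)
  if (length(object@seqs) > 0L && (is.null(ids) || anyNA(ids) || any(ids == "")))
    msg <- c(msg, "all loci must be named")
  if (!is.null(ids) && anyDuplicated(ids))
    msg <- c(msg, "locus identifiers must be unique")
  if (length(object@ranges) != 0L &&
      length(object@ranges) != length(object@seqs))
    msg <- c(msg, "'ranges' must be empty or parallel to 'seqs'")
  if (length(object@cellLines) != length(object@seqs))
    msg <- c(msg, "'cellLines' must be parallel to 'seqs'")
  bad <- grepl("[^ACGTN]", as.character(object@seqs))
  if (any(bad))
    msg <- c(msg, sprintf("sequences must be uppercase A/C/G/T/N (offending: %s)",
                          paste(head(ids[bad], 3L), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' ConsensusLibrary: subfamily consensus sequences with age classes
#'
#' @slot consensus Named [Biostrings::DNAStringSet] of subfamily consensus
#'   sequences.
#' @slot ageClass Named character vector mapping each subfamily name to an
#'   age class, one of `"J"`, `"S"`, `"Y"`, `"Ya5"`, `"Yb8"`, `"other"`.
#'
#' @seealso [syntheticConsensusLibrary()]
#' @export
setClass("ConsensusLibrary",
  representation(consensus = "DNAStringSet", ageClass = "character")
)

setValidity("ConsensusLibrary", function(object) {
  msg <- character(0)
  nm <- names(object@consensus)
  if (length(object@consensus) == 0L)
    msg <- c(msg, "library must contain at least one consensus")
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    msg <- c(msg, "consensus names must be unique and non-empty")
  if (any(Biostrings::width(object@consensus) == 0L))
    msg <- c(msg, "consensus sequences must be non-empty")
  if (!all(names(object@ageClass) %in% nm))
    msg <- c(msg, "ageClass names must be a subset of consensus names")
  ok <- c("J", "S", "Y", "Ya5", "Yb8", "other")
  if (!all(object@ageClass %in% ok))
    msg <- c(msg, sprintf("age classes must be one of %s",
                          paste(ok, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' KeyConfig: thresholds of the dichotomous classification key
#'
#' Thresholds for the four-parameter key used to triage loci into
#' potentially active vs inactive: percent divergence bins (boundaries at
#' 5 and 10 percent by default; above the upper bin the element is
#' classified retrotranspositionally inactive), minimum A-tail length
#' (inclusive), maximum unique-region length (inclusive) and maximum
#' percent A-tail disruption (inclusive).
#'
#' @slot divergenceBins Numeric length 2, strictly increasing percent
#'   breakpoints (default `c(5, 10)`).
#' @slot aTailMin Minimum A-tail length in bases for a pass (default 20,
#'   inclusive).
#' @slot uniqueMax Maximum unique-region length in bases for a pass
#'   (default 20, inclusive).
#' @slot disruptionMax Maximum percent A-tail disruption for a pass
#'   (default 10, inclusive).
#'
#' @seealso [keyConfig()], [applyKey()]
#' @export
setClass("KeyConfig",
  representation(
    divergenceBins = "numeric",
    aTailMin = "numeric",
    uniqueMax = "numeric",
    disruptionMax = "numeric"
  )
)

setValidity("KeyConfig", function(object) {
  msg <- character(0)
  if (length(object@divergenceBins) != 2L ||
      diff(object@divergenceBins) <= 0)
    msg <- c(msg, "divergenceBins must be two strictly increasing breakpoints")
  if (any(c(object@divergenceBins, object@aTailMin, object@uniqueMax,
            object@disruptionMax) <= 0))
    msg <- c(msg, "all thresholds must be positive")
  if (length(msg)) msg else TRUE
})

#' ScoreTables: per-feature multiplicative R factors for the ERP score
#'
#' Four piecewise-linear lookup tables mapping a feature value to a
#' retrotransposition-impact factor R in `[0, 1]`, plus a floor: the
#' minimum ERP assigned to any structurally intact locus. The ERP of a
#' locus is the product of the four factors (clamped below at the floor);
#' an ideal element — at the reference value of every table — scores 1.00.
#'
#' @slot divergence data.frame with columns `value` (percent divergence)
#'   and `R`; R non-increasing in divergence.
#' @slot aTail data.frame (`value` = A-tail length in bases, `R`);
#'   R non-decreasing up to the reference length.
#' @slot unique data.frame (`value` = unique-region length in bases, `R`);
#'   non-increasing.
#' @slot disruption data.frame (`value` = percent A-tail disruption, `R`);
#'   non-increasing.
#' @slot floor Minimum ERP for a structurally intact locus (default 1e-6).
#'
#' @seealso [defaultScoreTables()], [loadScoreTables()], [erpScore()]
#' @export
setClass("ScoreTables",
  representation(
    divergence = "data.frame",
    aTail = "data.frame",
    unique = "data.frame",
    disruption = "data.frame",
    floor = "numeric"
  )
)

.checkScoreTable <- function(tab, name, direction) {
  msg <- character(0)
  if (!all(c("value", "R") %in% colnames(tab)))
    return(sprintf("table '%s' must have columns 'value' and 'R'", name))
  if (nrow(tab) < 2L)
    msg <- c(msg, sprintf("table '%s' needs at least two anchor rows", name))
  if (is.unsorted(tab$value, strictly = TRUE))
    msg <- c(msg, sprintf("table '%s': values must be strictly increasing", name))
  bad <- which(tab$R < 0 | tab$R > 1)
  if (length(bad))
    msg <- c(msg, sprintf("table '%s': R outside [0,1] at rows %s",
                          name, paste(bad, collapse = ", ")))
  d <- diff(tab$R) * direction
  if (any(d < 0))
    msg <- c(msg, sprintf(
      "table '%s': R must be %s in value (offending rows %s)", name,
      if (direction > 0) "non-decreasing" else "non-increasing",
      paste(which(d < 0) + 1L, collapse = ", ")))
  msg
}

setValidity("ScoreTables", function(object) {
  msg <- c(
    .checkScoreTable(object@divergence, "divergence", -1),
    .checkScoreTable(object@aTail, "a_tail", +1),
    .checkScoreTable(object@unique, "unique", -1),
    .checkScoreTable(object@disruption, "disruption", -1)
  )
  if (length(object@floor) != 1L || object@floor < 0 || object@floor > 1)
    msg <- c(msg, "floor must be a single value in [0,1]")
  if (length(msg)) msg else TRUE
})
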