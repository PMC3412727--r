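## Synthetic dimeric test consensus (282 bp). Designed, not biological:
## - B-box motif GTTCGAAAC embedded at 0-based offset 72 (within the
##   default B-box search window 60-90 of the consensus frame);
## - A5-TACA-A6 linker at 0-based offset 132, splitting the element into
##   a left arm (0-131) and right arm (146-281), mimicking the dimeric
##   Alu architecture;
## - no TTT run and no TT[ACG]TT motif anywhere, so no single-base
##   substitution, insertion or deletion can create a TTTT pol III
##   terminator inside the body;
## - no A run of 5+ outside the linker; ends in GC (never A), keeping the
##   body / A-tail boundary unambiguous.
.BASE_CONSENSUS <- paste0(
  "CTGCAACGGCGAGATGCCGTTGGCAAGCACCTGTGCAGCGTACACCGGGG",
  "CAAGGACTTCCAGGGAATACGCGTTCGAAACCCGGGCCGTGCACGCGCCG",
  "AGAGGTGCAAAGCAATTCACGGCCCGCGCAAGAAAAATACAAAAAAGTCT",
  "ATGCAGAGGGCTACCCAGTCGTCCGCGCTTAGTGCAGCCGCCTGAGGGGG",
  "CAGAAGGCCGTGTTAGGGACACCTCGACCGATACGACAAGAAGGCCCGAC",
  "AAACCGCTAACCGCTCCCGGGAACACTAGAGC")

## fixed diagnostic substitution positions (0-based) per subfamily,
## chosen outside the B-box window, the linker and the final two bases
.DIAG_POSITIONS <- list(
  AluYa5 = c(5, 50, 153, 166, 243),
  AluYb8 = c(22, 23, 48, 174, 225, 233, 239, 276),
  AluS   = c(1, 8, 12, 18, 34, 40, 53, 54, 121, 175, 197, 204, 241, 249,
             250, 257, 267, 277),
  AluJ   = c(1, 8, 12, 17, 18, 34, 35, 40, 53, 54, 120, 121, 155, 164,
             167, 175, 189, 197, 198, 204, 221, 235, 241, 248, 249, 250,
             257, 260, 266, 267, 268, 277)
)

## substitution map for diagnostics: never introduces T (no terminator
## creation) and never A (no A-run creation)
.DIAG_SUB <- c(A = "G", C = "G", G = "C", T = "C")

.applyDiagnostics <- function(seq, pos0) {
  v <- strsplit(seq, "")[[1]]
  v[pos0 + 1L] <- .DIAG_SUB[v[pos0 + 1L]]
  paste(v, collapse = "")
}

#' Synthetic Alu subfamily consensus library
#'
#' A fully synthetic, self-contained consensus library used for testing
#' and simulation. It is NOT a biological Alu consensus: the base 282-bp
#' dimeric sequence (taken as the "AluY" reference) carries an embedded
#' B-box motif (`GTTCGAAAC` at consensus offset 72), an A5-TACA-A6 linker
#' joining two monomer arms, and is engineered so that no single-base
#' mutation can create a TTTT pol III terminator inside the body. The
#' other subfamilies are derived from it by fixed diagnostic
#' substitutions (5 for AluYa5, 8 for AluYb8, 18 for AluS, 32 for AluJ),
#' mirroring how real subfamilies are defined by diagnostic nucleotides.
#' Real (e.g. Repbase) consensuses are supplied by the user via
#' [ConsensusLibrary()].
#'
#' @return A [ConsensusLibrary-class] with subfamilies `AluJ`, `AluS`,
#'   `AluY`, `AluYa5`, `AluYb8` and the matching age classes.
#' @examples
#' lib <- syntheticConsensusLibrary()
#' ageClasses(lib)
#' @export
syntheticConsensusLibrary <- function() {
  seqs <- c(
    AluJ = .applyDiagnostics(.BASE_CONSENSUS, .DIAG_POSITIONS$AluJ),
    AluS = .applyDiagnostics(.BASE_CONSENSUS, .DIAG_POSITIONS$AluS),
    AluY = .BASE_CONSENSUS,
    AluYa5 = .applyDiagnostics(.BASE_CONSENSUS, .DIAG_POSITIONS$AluYa5),
    AluYb8 = .applyDiagnostics(.BASE_CONSENSUS, .DIAG_POSITIONS$AluYb8)
  )
  ConsensusLibrary(seqs, ageClass = c(AluJ = "J", AluS = "S", AluY = "Y",
                                      AluYa5 = "Ya5", AluYb8 = "Yb8"))
}
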