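#' Find the first RNA polymerase III terminator
#'
#' A pol III terminator is a run of `minRun` (default 4) or more
#' consecutive thymidines on the sense strand. Returns the 0-based offset
#' of the first position, at or after `from`, at which such a run begins,
#' or `NA` if there is none.
#'
#' @param seq Nucleotide string (character or [Biostrings::DNAString]).
#' @param from 0-based offset to start scanning at.
#' @param minRun Minimum run length (default 4).
#' @return Integer 0-based offset, or `NA_integer_`.
#' @examples
#' findTerminator("GCATTTTG")    # 3
#' findTerminator("TTTATTTA")    # NA
#' @export
findTerminator <- function(seq, from = 0L, minRun = 4L) {
  seq <- as.character(seq)
  from <- as.integer(from)
  n <- nchar(seq)
  if (is.na(from) || from < 0L || from > n)
    stop("'from' offset outside sequence")
  if (from == n) return(NA_integer_)
  m <- regexpr(paste0("T{", minRun, ",}"), substr(seq, from + 1L, n))
  if (m == -1L) return(NA_integer_)
  from + as.integer(m) - 1L
}

.nucSubMat <- function(match = 1, mismatch = -1) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", "N"] <- mismatch  # N is always a mismatch, even against N
  m
}

## Align every locus against every consensus (local in the locus, global
## in the consensus) in one pairwiseAlignment call per consensus, pick
## the best consensus per locus (ties: lexicographic name), and compute
## divergence, identity coverage per monomer arm, the body span, and the
## locus coordinates of the consensus-frame B-box window — all from the
## vectorized alignment accessors.
##
## Coordinate notes: insertion()/deletion() ranges of indel() are in
## gapped alignment-column space; a column x maps to consensus position
## x - (insertion width before x) and to locus position
## patternStart - 1 + x - (deletion width up to x).
.locateBodies <- function(seqs, library, match = 1, mismatch = -1,
                          gapOpening = 5, gapExtension = 1,
                          bboxWindow = c(60L, 90L), motifLen = 9L) {
  stopifnot(is(library, "ConsensusLibrary"), length(library) > 0L)
  n <- length(seqs)
  pats <- Biostrings::DNAStringSet(seqs)
  cons <- consensusSeqs(library)
  subMat <- .nucSubMat(match, mismatch)
  alns <- lapply(seq_along(cons), function(j)
    Biostrings::pairwiseAlignment(
      pattern = pats, subject = cons[[j]], type = "local-global",
      substitutionMatrix = subMat, gapOpening = gapOpening,
      gapExtension = gapExtension))
  scores <- matrix(vapply(alns, Biostrings::score, numeric(n)), nrow = n)
  nameOrd <- order(names(cons))
  best <- apply(scores[, nameOrd, drop = FALSE], 1L,
                function(s) nameOrd[which.max(s)])
  out <- vector("list", n)
  for (j in unique(best)) {
    idx <- which(best == j)
    a <- alns[[j]][idx]
    consLen <- Biostrings::width(cons[j])
    half <- as.integer(ceiling(consLen / 2))
    nm <- unname(Biostrings::nmismatch(a))
    ni <- Biostrings::nindel(a)
    insL <- unname(Biostrings::insertion(ni)[, "Length"])
    delL <- unname(Biostrings::deletion(ni)[, "Length"])
    delW <- unname(Biostrings::deletion(ni)[, "WidthSum"])
    ind <- Biostrings::indel(a)
    insR <- Biostrings::insertion(ind)
    delR <- Biostrings::deletion(ind)
    ps <- Biostrings::start(Biostrings::pattern(a))
    pe <- Biostrings::end(Biostrings::pattern(a))
    mt <- Biostrings::mismatchTable(a)
    mmBySeq <- split(mt$SubjectStart,
                     factor(mt$PatternId, levels = seq_along(idx)))
    w1 <- min(bboxWindow[1] + 1L, consLen)
    w2 <- min(bboxWindow[2] + motifLen, consLen)
    for (k in seq_along(idx)) {
      iS <- Biostrings::start(insR[[k]]); iW <- Biostrings::width(insR[[k]])
      dS <- Biostrings::start(delR[[k]]); dE <- Biostrings::end(delR[[k]])
      dW <- dE - dS + 1L
      insBefore <- function(x) if (length(iS)) sum(iW[iS < x]) else 0L
      # deletions in consensus coordinates
      dSsub <- dS - vapply(dS, insBefore, 1L)
      dEsub <- dE - vapply(dE, insBefore, 1L)
      delIn1 <- sum(pmax(0L, pmin(dEsub, half) - pmax(dSsub, 1L) + 1L))
      mm <- mmBySeq[[k]]
      match1 <- (half - delIn1) - sum(mm <= half)
      match2 <- (consLen - half - (delW[k] - delIn1)) - sum(mm > half)
      # consensus position -> 0-based locus offset
      mapToLocus <- function(cpos) {
        x <- cpos
        repeat {
          x2 <- cpos + insBefore(x + 1L)
          if (x2 == x) break
          x <- x2
        }
        inDel <- which(dS <= x & x <= dE)
        if (length(inDel)) x <- dS[inDel[1L]] - 1L
        dBefore <- if (length(dS)) sum(dW[dE <= x]) +
          sum(pmax(0L, x - dS[dS <= x & dE > x] + 1L)) else 0L
        ps[k] - 1L + x - dBefore - 1L
      }
      bf <- mapToLocus(w1)
      bt <- max(bf, mapToLocus(w2) - (motifLen - 1L))
      out[[idx[k]]] <- list(
        subfamily = names(cons)[j],
        age_class = ageClasses(library)[[names(cons)[j]]],
        score = scores[idx[k], j],
        body_start = ps[k] - 1L,
        body_end = pe[k],
        divergence_pct = 100 * (nm[k] + insL[k] + delL[k]) / consLen,
        coverage = match1 + match2,
        cov_half1 = match1 / half,
        cov_half2 = match2 / (consLen - half),
        consensus_len = consLen,
        bbox_from = bf,
        bbox_to = bt)
    }
  }
  out
}

#' Locate the Alu body by alignment against a consensus library
#'
#' Aligns the locus against every consensus with a pairwise alignment
#' that is global in the consensus and local in the locus. The
#' best-scoring consensus (ties broken by lexicographic subfamily name)
#' defines the subfamily and the body span; percent divergence is
#' `100 * (mismatches + indel events) / aligned consensus columns`, where
#' a contiguous gap run counts as a single event. N bases count as
#' mismatches. Coverage is identity coverage: the number of consensus
#' positions aligned to an identical locus base, reported overall and
#' per monomer arm (consensus half).
#'
#' @param seq Locus sequence (element sense).
#' @param library A [ConsensusLibrary-class].
#' @param match,mismatch,gapOpening,gapExtension Alignment scoring
#'   (defaults +1 / -1 / 5 / 1; gap penalties are costs).
#' @param bboxWindow 0-based consensus offsets `c(from, to)` within which
#'   the B-box motif must start; the window is mapped through the
#'   alignment to locus coordinates and returned as `bbox_from` /
#'   `bbox_to`.
#' @param motifLen Length of the B-box motif, used to extend the mapped
#'   window.
#' @return List: `subfamily`, `age_class`, `score`, `body_start`,
#'   `body_end` (0-based half-open in the locus), `divergence_pct`,
#'   `coverage`, `cov_half1`, `cov_half2` (per-arm identity-coverage
#'   fractions), `consensus_len`, `bbox_from`, `bbox_to`.
#' @examples
#' lib <- syntheticConsensusLibrary()
#' loc <- locateBody(as.character(consensusSeqs(lib)[["AluY"]]), lib)
#' loc$divergence_pct  # 0: identical to its consensus
#' @export
locateBody <- function(seq, library, match = 1, mismatch = -1,
                       gapOpening = 5, gapExtension = 1,
                       bboxWindow = c(60L, 90L), motifLen = 9L) {
  .locateBodies(as.character(seq), library, match = match,
                mismatch = mismatch, gapOpening = gapOpening,
                gapExtension = gapExtension, bboxWindow = bboxWindow,
                motifLen = motifLen)[[1L]]
}

#' Measure the A-tail downstream of the element body
#'
#' Scans rightwards from `bodyEnd`, stopping at the first of: three
#' consecutive non-A bases, a pol III terminator (per
#' [findTerminator()]), or the end of the sequence; trailing non-A bases
#' are then trimmed. Disruption is the percent of non-A bases within the
#' trimmed tail (0 for an empty tail). The tail never extends past a
#' terminator start.
#'
#' @param seq Locus sequence.
#' @param bodyEnd 0-based exclusive end of the element body.
#' @param minRun Terminator run length (default 4).
#' @return List: `a_tail_len`, `a_tail_disruption_pct`, `tail_end`
#'   (0-based exclusive offset of the trimmed tail).
#' @examples
#' measureATail("AAAAAAGAGAAAATTTTCC", 0)  # len 13, disruption 15.4%
#' @export
measureATail <- function(seq, bodyEnd, minRun = 4L) {
  seq <- as.character(seq)
  bodyEnd <- as.integer(bodyEnd)
  n <- nchar(seq)
  if (is.na(bodyEnd) || bodyEnd < 0L || bodyEnd > n)
    stop("'bodyEnd' offset outside sequence")
  stop_abs <- n
  term <- findTerminator(seq, bodyEnd, minRun)
  if (!is.na(term)) stop_abs <- min(stop_abs, term)
  v <- strsplit(substr(seq, bodyEnd + 1L, n), "")[[1]]
  nonA <- v != "A"
  if (length(v) >= 3L) {
    r <- rle(nonA)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= 3L)
    if (length(hit))
      stop_abs <- min(stop_abs, bodyEnd + ends[hit[1L]] - r$lengths[hit[1L]])
  }
  k <- stop_abs - bodyEnd
  tail <- if (k > 0L) v[seq_len(k)] else character(0)
  lastA <- if (any(tail == "A")) max(which(tail == "A")) else 0L
  tail <- tail[seq_len(lastA)]
  len <- length(tail)
  list(
    a_tail_len = len,
    a_tail_disruption_pct = if (len > 0L) 100 * sum(tail != "A") / len else 0,
    tail_end = bodyEnd + len)
}

#' Measure the unique region between A-tail and terminator
#'
#' The unique region runs from the tail end to the start of the first
#' pol III terminator within `window` bases; if no terminator is found
#' there, its length is capped at `min(window, remaining sequence)` and
#' `terminator_found` is `FALSE`.
#'
#' @param seq Locus sequence.
#' @param tailEnd 0-based exclusive end of the (trimmed) A-tail.
#' @param window Maximum flank window in bases (default 300).
#' @param minRun Terminator run length (default 4).
#' @return List: `unique_len`, `terminator_found`.
#' @export
measureUniqueRegion <- function(seq, tailEnd, window = 300L, minRun = 4L) {
  seq <- as.character(seq)
  tailEnd <- as.integer(tailEnd)
  window <- as.integer(window)
  n <- nchar(seq)
  if (is.na(tailEnd) || tailEnd < 0L || tailEnd > n)
    stop("'tailEnd' offset outside sequence")
  term <- findTerminator(seq, tailEnd, minRun)
  if (!is.na(term) && term - tailEnd <= window)
    return(list(unique_len = term - tailEnd, terminator_found = TRUE))
  list(unique_len = min(window, n - tailEnd), terminator_found = FALSE)
}

#' Structural filter: dimeric-Alu requirement and internal terminators
#'
#' Rejects loci that do not fit the standard dimeric Alu structure
#' (FLAM/FRAM-like monomers and partial elements) and loci whose body
#' contains an internal pol III terminator (which would produce
#' truncated transcripts). Coverage is identity coverage from
#' [locateBody()]: a locus is monomeric when exactly one of the two
#' consensus halves reaches `halfFrac`; partial when overall coverage
#' falls below `minCoverage` bases or both halves are undercovered.
#'
#' @param loc Result of [locateBody()].
#' @param seq Locus sequence.
#' @param minCoverage Minimum identity-covered consensus bases
#'   (default 200).
#' @param halfFrac Minimum identity-covered fraction of each consensus
#'   half (default 0.5).
#' @param minRun Terminator run length (default 4).
#' @return List: `structure_ok` (logical), `reject_reason`
#'   (`NA_character_`, `"monomeric"`, `"partial"`, or
#'   `"internal_terminator"`).
#' @export
structuralFilter <- function(loc, seq, minCoverage = 200L, halfFrac = 0.5,
                             minRun = 4L) {
  h1 <- loc$cov_half1 >= halfFrac
  h2 <- loc$cov_half2 >= halfFrac
  if (xor(h1, h2))
    return(list(structure_ok = FALSE, reject_reason = "monomeric"))
  if (loc$coverage < minCoverage || !(h1 && h2))
    return(list(structure_ok = FALSE, reject_reason = "partial"))
  t <- findTerminator(seq, loc$body_start, minRun)
  if (!is.na(t) && t + minRun <= loc$body_end)
    return(list(structure_ok = FALSE, reject_reason = "internal_terminator"))
  list(structure_ok = TRUE, reject_reason = NA_character_)
}

#' Test for a B-box internal promoter motif
#'
#' Returns `TRUE` iff the degenerate B-box motif (IUPAC, default
#' `GWTCRANNC`) starts within the 0-based locus offsets `[from, to]`.
#' [extractFeatures()] derives that window by mapping the configured
#' consensus-frame window (default offsets 60-90) through the alignment.
#'
#' @param seq Locus sequence.
#' @param from,to 0-based offsets bounding allowed motif start positions.
#' @param motif IUPAC motif string.
#' @return Logical.
#' @export
hasBBox <- function(seq, from, to, motif = "GWTCRANNC") {
  seq <- as.character(seq)
  if (is.na(from) || is.na(to) || to < from) return(FALSE)
  end <- min(nchar(seq), to + nchar(motif))
  if (end - from < nchar(motif)) return(FALSE)
  region <- Biostrings::DNAString(substr(seq, from + 1L, end))
  hits <- Biostrings::matchPattern(Biostrings::DNAString(motif), region,
                                   fixed = FALSE)
  any(Biostrings::start(hits) <= to - from + 1L)
}

#' Extract the full feature vector for every locus
#'
#' Runs the whole per-locus feature stage: N-content screen, body
#' location and subfamily assignment by alignment, structural filtering,
#' A-tail and unique-region measurement, and the B-box scan. Rejected
#' loci keep whatever features were computable and carry a
#' `reject_reason`.
#'
#' @param loci An [AluLocusSet-class].
#' @param library A [ConsensusLibrary-class].
#' @param flank Unique-region window in bases (default 300).
#' @param minRun Terminator run length (default 4).
#' @param maxNFrac Maximum tolerated fraction of N bases (default 0.10).
#' @param minCoverage,halfFrac Structural-filter settings; see
#'   [structuralFilter()].
#' @param bboxWindow 0-based consensus-frame window for the B-box start
#'   (default `c(60, 90)`).
#' @param bboxMotif IUPAC B-box motif (default `GWTCRANNC`).
#' @param match,mismatch,gapOpening,gapExtension Alignment scoring.
#' @return A [S4Vectors::DataFrame] with one row per locus: `locus_id`,
#'   `subfamily`, `age_class`, `divergence_pct`, `body_start`,
#'   `body_end`, `a_tail_len`, `a_tail_disruption_pct`, `unique_len`,
#'   `terminator_found`, `has_b_box`, `structure_ok`, `reject_reason`.
#' @examples
#' lib <- syntheticConsensusLibrary()
#' co <- generateCohort(3, seed = 42)
#' extractFeatures(co$loci, lib)
#' @export
extractFeatures <- function(loci, library, flank = 300L, minRun = 4L,
                            maxNFrac = 0.10, minCoverage = 200L,
                            halfFrac = 0.5, bboxWindow = c(60L, 90L),
                            bboxMotif = "GWTCRANNC",
                            match = 1, mismatch = -1, gapOpening = 5,
                            gapExtension = 1) {
  stopifnot(is(loci, "AluLocusSet"))
  seqs <- as.character(lociSeqs(loci))
  n <- length(seqs)
  cols <- list(
    locus_id = if (n) lociIds(loci) else character(0),
    subfamily = rep(NA_character_, n), age_class = rep(NA_character_, n),
    divergence_pct = rep(NA_real_, n),
    body_start = rep(NA_integer_, n), body_end = rep(NA_integer_, n),
    a_tail_len = rep(NA_integer_, n),
    a_tail_disruption_pct = rep(NA_real_, n),
    unique_len = rep(NA_integer_, n), terminator_found = rep(NA, n),
    has_b_box = rep(NA, n), structure_ok = rep(FALSE, n),
    reject_reason = rep(NA_character_, n))
  if (n == 0L) return(do.call(S4Vectors::DataFrame, cols))
  nFrac <- vapply(seqs, function(s)
    lengths(regmatches(s, gregexpr("N", s, fixed = TRUE))) / nchar(s), 1,
    USE.NAMES = FALSE)
  tooN <- nFrac > maxNFrac
  cols$reject_reason[tooN] <- "excess_N"
  todo <- which(!tooN)
  if (length(todo)) {
    locs <- .locateBodies(seqs[todo], library, match = match,
                          mismatch = mismatch, gapOpening = gapOpening,
                          gapExtension = gapExtension,
                          bboxWindow = bboxWindow,
                          motifLen = nchar(bboxMotif))
    for (k in seq_along(todo)) {
      i <- todo[k]
      loc <- locs[[k]]
      s <- seqs[i]
      if (loc$score <= 0) {
        cols$reject_reason[i] <- "no_consensus_hit"
        next
      }
      cols$subfamily[i] <- loc$subfamily
      cols$age_class[i] <- loc$age_class
      cols$divergence_pct[i] <- loc$divergence_pct
      cols$body_start[i] <- loc$body_start
      cols$body_end[i] <- loc$body_end
      filt <- structuralFilter(loc, s, minCoverage = minCoverage,
                               halfFrac = halfFrac, minRun = minRun)
      cols$structure_ok[i] <- filt$structure_ok
      cols$reject_reason[i] <- filt$reject_reason
      tail <- measureATail(s, loc$body_end, minRun = minRun)
      cols$a_tail_len[i] <- tail$a_tail_len
      cols$a_tail_disruption_pct[i] <- tail$a_tail_disruption_pct
      uniq <- measureUniqueRegion(s, tail$tail_end, window = flank,
                                  minRun = minRun)
      cols$unique_len[i] <- uniq$unique_len
      cols$terminator_found[i] <- uniq$terminator_found
      cols$has_b_box[i] <- hasBBox(s, loc$bbox_from, loc$bbox_to,
                                   motif = bboxMotif)
    }
  }
  do.call(S4Vectors::DataFrame, cols)
}
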