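#' Specification of one synthetic Alu-like locus
#'
#' Describes the ground-truth construction of a single synthetic locus:
#' a mutated copy of a subfamily consensus (the body), followed by an
#' A-tail with a controlled non-A disruption fraction, a unique 3' region
#' free of premature terminators, and a run-of-T pol III terminator.
#'
#' @param subfamily Subfamily name; must match a consensus in the library
#'   used at generation time.
#' @param divergence Target percent divergence of the body from its
#'   consensus (substitution + indel events per consensus base, times 100).
#' @param aTailLen A-tail length in bases.
#' @param disruption Target percent of non-A bases within the tail;
#'   realized as the nearest achievable count.
#' @param uniqueLen Length in bases of the unique region between tail and
#'   terminator.
#' @param terminatorLen Length of the terminal T run (>= 4).
#' @param structure `"dimeric"` (normal), `"monomeric"` (FLAM/FRAM-like
#'   left-arm-only decoy) or `"internally_terminated"` (dimeric body with
#'   a TTTT run planted mid-body).
#' @param seed Integer seed making the construction reproducible, or
#'   `NULL` to draw from the current RNG stream.
#'
#' @return A `LocusSpec` (validated list).
#' @examples
#' locusSpec(divergence = 5, aTailLen = 25, disruption = 8, uniqueLen = 15,
#'           seed = 7)
#' @export
locusSpec <- function(subfamily = "AluY", divergence = 0, aTailLen = 30,
                      disruption = 0, uniqueLen = 50, terminatorLen = 6,
                      structure = c("dimeric", "monomeric",
                                    "internally_terminated"),
                      seed = NULL) {
  structure <- match.arg(structure)
  stopifnot(divergence >= 0, aTailLen >= 0,
            disruption >= 0, disruption <= 100,
            uniqueLen >= 0, terminatorLen >= 4)
  out <- list(subfamily = subfamily, divergence = divergence,
              aTailLen = as.integer(aTailLen), disruption = disruption,
              uniqueLen = as.integer(uniqueLen),
              terminatorLen = as.integer(terminatorLen),
              structure = structure, seed = seed)
  class(out) <- "LocusSpec"
  out
}

## mutate a body sequence: nEvents = round(div% * L), 10% of events are
## single-base indels (50/50 insertion/deletion), the rest substitutions.
## Positions are pairwise >= 2 apart and never in the last ten bases
## (the intact terminal block anchors the alignment at the body/tail
## junction, so the extracted body end is exact), and substituted or
## inserted bases are drawn from {A,C,G}; together with the engineered
## consensus this guarantees no TTTT is created and each event stays a
## distinct alignment event, so realized divergence is exact.
.mutateBody <- function(body, divergence, indelFrac = 0.1) {
  v <- strsplit(body, "")[[1]]
  L <- length(v)
  nEvents <- round(divergence / 100 * L)
  if (nEvents == 0L)
    return(list(seq = body, events = 0L, consensusLen = L))
  m <- L - 10L
  if (m < 1L || m - (nEvents - 1L) < nEvents)
    stop("degenerate body: divergence too high for a ", L, "-base body")
  pos <- .sampleSpaced(nEvents, m)
  nIndel <- round(indelFrac * nEvents)
  isIndel <- rep(FALSE, nEvents)
  if (nIndel > 0L)
    isIndel[sample.int(nEvents, nIndel)] <- TRUE
  isDel <- isIndel & (runif(nEvents) < 0.5)
  out <- vector("list", nEvents + 1L)
  prev <- 1L
  for (k in seq_len(nEvents)) {
    p <- pos[k]
    out[[k]] <- if (p > prev) v[prev:(p - 1L)] else character(0)
    if (!isIndel[k]) {
      out[[k]] <- c(out[[k]], sample(setdiff(c("A", "C", "G"), v[p]), 1L))
    } else if (isDel[k]) {
      # drop v[p]
    } else {
      out[[k]] <- c(out[[k]], sample(c("A", "C", "G"), 1L), v[p])
    }
    prev <- p + 1L
  }
  out[[nEvents + 1L]] <- v[prev:L]
  mut <- paste(unlist(out), collapse = "")
  if (nchar(mut) < 50L)
    stop("degenerate body: mutated body collapsed below 50 bases")
  list(seq = mut, events = nEvents, consensusLen = L)
}

## A-tail with k = round(disrupt% * len) non-A bases, pairwise spacing
## >= 2 and never at the final tail position (keeps the extraction rule's
## tail length exactly equal to the constructed length)
.makeTail <- function(len, disruption) {
  if (len == 0L)
    return(list(seq = "", k = 0L))
  k <- round(disruption / 100 * len)
  v <- rep("A", len)
  if (k > 0L) {
    if (len - 1L - (k - 1L) < k)
      stop("disruption unachievable: too many non-A bases for tail length ", len)
    at <- .sampleSpaced(k, len - 1L)
    v[at] <- sample(c("C", "G", "T"), k, replace = TRUE)
  }
  list(seq = paste(v, collapse = ""), k = k)
}

## unique region: first up-to-3 bases are C/G (so the tail scan stops at
## its true boundary), Ts are isolated and never terminal (no premature
## or shifted terminator)
.makeUnique <- function(len) {
  if (len == 0L) return("")
  v <- character(len)
  head_n <- min(3L, len)
  v[seq_len(head_n)] <- sample(c("C", "G"), head_n, replace = TRUE)
  if (len > head_n) {
    v[(head_n + 1L):len] <- sample(c("A", "C", "G", "T"), len - head_n,
                                   replace = TRUE,
                                   prob = c(0.3, 0.3, 0.3, 0.1))
    for (i in (head_n + 1L):len)
      if (v[i] == "T" && (i == len || v[i - 1L] == "T"))
        v[i] <- "C"
  }
  paste(v, collapse = "")
}

#' Generate one synthetic Alu-like locus with known ground truth
#'
#' Builds `mutated body + A-tail + unique region + T-run terminator`
#' according to a [locusSpec()]. The construction is engineered so that
#' the feature-extraction stage can recover the ground truth exactly
#' (tail and unique lengths) or near-exactly (divergence): mutations
#' never create a TTTT terminator, never touch the last two body bases,
#' and stay pairwise non-adjacent; tail disruptions are isolated and
#' never terminal; the unique region opens with C/G bases and carries
#' only isolated Ts. Identical `(spec, consensus)` with the same seed
#' give byte-identical output.
#'
#' @param spec A [locusSpec()].
#' @param consensus Consensus sequence (character or
#'   [Biostrings::DNAString]) for the spec's subfamily.
#' @return A `TruthRecord`: list with `spec`, `sequence`,
#'   `body_end` (0-based exclusive offset of the body/tail boundary),
#'   `realized_divergence_pct` and `realized_disruption_pct` (both exact
#'   by direct counting of placed events).
#' @examples
#' lib <- syntheticConsensusLibrary()
#' tr <- generateLocus(locusSpec(divergence = 5, aTailLen = 25,
#'                               disruption = 8, seed = 7),
#'                     consensusSeqs(lib)[["AluY"]])
#' tr$realized_disruption_pct
#' @export
generateLocus <- function(spec, consensus) {
  stopifnot(inherits(spec, "LocusSpec"))
  consensus <- as.character(consensus)
  if (nchar(consensus) == 0L) stop("consensus must be non-empty")
  .withSeed(spec$seed, {
    body0 <- switch(spec$structure,
      dimeric = consensus,
      monomeric = substr(consensus, 1L, min(132L, nchar(consensus))),
      internally_terminated = consensus)
    mut <- .mutateBody(body0, spec$divergence)
    body <- mut$seq
    if (spec$structure == "internally_terminated") {
      at <- nchar(body) %/% 2L
      body <- paste0(substr(body, 1L, at), "TTTT",
                     substr(body, at + 1L, nchar(body)))
    }
    tail <- .makeTail(spec$aTailLen, spec$disruption)
    uniq <- .makeUnique(spec$uniqueLen)
    term <- strrep("T", spec$terminatorLen)
    rec <- list(
      locus_id = NA_character_,
      spec = spec,
      sequence = paste0(body, tail$seq, uniq, term),
      body_end = nchar(body),
      realized_divergence_pct = 100 * mut$events / mut$consensusLen,
      realized_disruption_pct = if (spec$aTailLen > 0)
        100 * tail$k / spec$aTailLen else 0
    )
    class(rec) <- "TruthRecord"
    rec
  })
}

#' Default sampler of locus specifications for cohort simulation
#'
#' Emulates a cohort of pol III-bound Alu loci: subfamily proportions
#' default to the bound-locus distribution (88.4% S+J split between AluJ
#' and AluS, 9.8% AluY, 1.2% AluYa5, 0.6% AluYb8), divergence drawn by
#' age class (older subfamilies more diverged), and realistic tail,
#' disruption, unique-region and terminator ranges.
#'
#' @param proportions Named sampling probabilities over subfamilies.
#' @param divergenceRanges Named list of `c(lo, hi)` percent-divergence
#'   ranges per subfamily.
#' @param tailRange,uniqueRange Integer ranges sampled uniformly.
#' @param disruptionMaxPct Upper bound of the uniform disruption draw.
#' @return A function of no arguments returning a [locusSpec()].
#' @export
defaultLocusSampler <- function(
    proportions = c(AluJ = 0.30, AluS = 0.584, AluY = 0.098,
                    AluYa5 = 0.012, AluYb8 = 0.006),
    divergenceRanges = list(AluJ = c(8, 16), AluS = c(5, 12),
                            AluY = c(1, 6), AluYa5 = c(0, 3),
                            AluYb8 = c(0, 3)),
    tailRange = c(5L, 60L), uniqueRange = c(0L, 80L),
    disruptionMaxPct = 20) {
  force(proportions); force(divergenceRanges)
  function() {
    sf <- sample(names(proportions), 1L, prob = proportions)
    dr <- divergenceRanges[[sf]]
    locusSpec(
      subfamily = sf,
      divergence = runif(1L, dr[1], dr[2]),
      aTailLen = sample(tailRange[1]:tailRange[2], 1L),
      disruption = runif(1L, 0, disruptionMaxPct),
      uniqueLen = sample(uniqueRange[1]:uniqueRange[2], 1L),
      terminatorLen = sample(4:8, 1L),
      structure = "dimeric", seed = NULL)
  }
}

#' Generate a cohort of synthetic loci with ground truth and fixtures
#'
#' Generates `n` loci from a spec sampler, assigns synthetic genomic
#' coordinates (one artificial contig, non-overlapping, random strand)
#' and cell lines, optionally plants a chosen number of loci in two cell
#' lines at identical coordinates (for duplicate-accounting tests), and
#' optionally writes FASTA / BED6 / TSV-truth fixture files.
#'
#' @param n Number of distinct loci (>= 1).
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of `(n, seed, sampler, library)`.
#' @param sampler A function returning a [locusSpec()] per draw; default
#'   [defaultLocusSampler()].
#' @param library A [ConsensusLibrary-class]; default
#'   [syntheticConsensusLibrary()].
#' @param cellLineNames Labels to assign loci to.
#' @param nShared Number of loci planted in exactly two cell lines.
#' @param dir If non-NULL, directory to write `<prefix>.fa`,
#'   `<prefix>.bed`, `<prefix>_truth.tsv` and per-cell-line BED files.
#' @param prefix Basename prefix for fixture files.
#'
#' @return List with `loci` (an [AluLocusSet-class] of the `n` unique
#'   loci, with coordinates and cell lines), `truth` (data.frame aligned
#'   1:1 with the FASTA records), `records` (list of `TruthRecord`),
#'   `byCellLine` (named list of `AluLocusSet`, one per cell line, in
#'   which shared loci appear once per line) and `files`.
#' @examples
#' co <- generateCohort(10, seed = 1)
#' co$truth$a_tail_len
#' @export
generateCohort <- function(n, seed, sampler = defaultLocusSampler(),
                           library = syntheticConsensusLibrary(),
                           cellLineNames = c("HeLa", "K562", "IMR90", "Jurkat"),
                           nShared = 0L, dir = NULL, prefix = "cohort") {
  stopifnot(n >= 1L, nShared <= n, nShared == 0L || length(cellLineNames) >= 2L)
  cons <- as.character(consensusSeqs(library))
  .withSeed(seed, {
    records <- vector("list", n)
    for (i in seq_len(n)) {
      spec <- sampler()
      if (!spec$subfamily %in% names(cons))
        stop("sampler produced unknown subfamily ", spec$subfamily)
      spec$seed <- NULL
      rec <- generateLocus(spec, cons[[spec$subfamily]])
      rec$locus_id <- sprintf("locus_%05d", i)
      records[[i]] <- rec
    }
    widths <- vapply(records, function(r) nchar(r$sequence), 1L)
    starts <- cumsum(c(0L, head(widths, -1L) + 100L))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    shared <- if (nShared > 0L) sort(sample.int(n, nShared)) else integer(0)
    lines <- vector("list", n)
    for (i in seq_len(n))
      lines[[i]] <- sample(cellLineNames, if (i %in% shared) 2L else 1L)
    gr <- GenomicRanges::GRanges(
      seqnames = "chrSim",
      ranges = IRanges::IRanges(start = starts + 1L, width = widths),
      strand = strands)
    names(gr) <- vapply(records, `[[`, "", "locus_id")
    loci <- AluLocusSet(
      setNames(vapply(records, `[[`, "", "sequence"), names(gr)),
      ranges = gr, cellLines = lines)
    truth <- data.frame(
      locus_id = lociIds(loci),
      subfamily = vapply(records, function(r) r$spec$subfamily, ""),
      divergence_pct = vapply(records, `[[`, 1, "realized_divergence_pct"),
      a_tail_len = vapply(records, function(r) r$spec$aTailLen, 1L),
      a_tail_disruption_pct = vapply(records, `[[`, 1,
                                     "realized_disruption_pct"),
      unique_len = vapply(records, function(r) r$spec$uniqueLen, 1L),
      structure = vapply(records, function(r) r$spec$structure, ""),
      cell_lines = vapply(lines, paste, "", collapse = ","),
      stringsAsFactors = FALSE)
    byCellLine <- lapply(setNames(nm = cellLineNames), function(cl) {
      keep <- vapply(lines, function(x) cl %in% x, TRUE)
      loci[which(keep)]
    })
    byCellLine <- byCellLine[vapply(byCellLine, length, 1L) > 0L]
    files <- character(0)
    if (!is.null(dir)) {
      if (!dir.exists(dir) &&
          !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", dir)
      fa <- file.path(dir, paste0(prefix, ".fa"))
      writeLociFasta(loci, fa)
      bed <- file.path(dir, paste0(prefix, ".bed"))
      .writeBed6(gr, bed)
      tsv <- file.path(dir, paste0(prefix, "_truth.tsv"))
      utils::write.table(truth, tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(fasta = fa, bed = bed, truth = tsv)
      for (cl in names(byCellLine)) {
        f <- file.path(dir, sprintf("%s_%s.bed", prefix, cl))
        .writeBed6(lociRanges(byCellLine[[cl]]), f)
        files[paste0("bed_", cl)] <- f
      }
    }
    list(loci = loci, truth = truth, records = records,
         byCellLine = byCellLine, files = files)
  })
}

.writeBed6 <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (is.null(names(gr))) "." else names(gr),
    score = 0L,
    strand = as.character(GenomicRanges::strand(gr)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
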