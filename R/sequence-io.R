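#' Write loci to FASTA
#'
#' Writes 60-column wrapped FASTA. Cell-line assignments are serialized
#' into the description as `cell_lines=a,b`, the format
#' [loadLociFromFasta()] parses back.
#'
#' @param loci An [AluLocusSet-class].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
writeLociFasta <- function(loci, path) {
  seqs <- lociSeqs(loci)
  cl <- cellLines(loci)
  hasCl <- lengths(cl) > 0L
  nm <- lociIds(loci)
  nm[hasCl] <- paste0(nm[hasCl], " cell_lines=",
                      vapply(cl[hasCl], paste, "", collapse = ","))
  names(seqs) <- nm
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Load loci from a FASTA file
#'
#' One locus per record; coordinates are absent. The first whitespace
#' token of the header is the locus id; a description field
#' `cell_lines=a,b` is parsed into the cell-line set. Lowercase sequence
#' is normalized to uppercase.
#'
#' @param path FASTA file.
#' @return An [AluLocusSet-class].
#' @export
loadLociFromFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L)
    stop("empty FASTA file: ", path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  cl <- lapply(headers, function(h) {
    m <- regmatches(h, regexpr("cell_lines=[^\\s]+", h, perl = TRUE))
    if (length(m)) strsplit(sub("^cell_lines=", "", m), ",")[[1]]
    else character(0)
  })
  AluLocusSet(setNames(as.character(seqs), ids), cellLines = cl)
}

#' Load loci from BED intervals plus a genome FASTA
#'
#' Extracts each BED6 interval and appends up to `flank` bases of
#' downstream genomic sequence, downstream in *element* orientation: for
#' a `+` locus the flank follows the interval end; for a `-` locus it
#' precedes the interval start and the whole stretch is
#' reverse-complemented, so `body_plus_flank` is always element-sense
#' with the A-tail and terminator downstream. Flanks running off a
#' contig edge are truncated with a warning.
#'
#' @param bed BED6 file (0-based half-open; name column used as locus id).
#' @param genome Genome FASTA file, or a named [Biostrings::DNAStringSet].
#' @param flank Downstream flank length in bases (default 300).
#' @return An [AluLocusSet-class] with coordinates.
#' @export
loadLociFromBed <- function(bed, genome, flank = 300L) {
  gr <- tryCatch(rtracklayer::import(bed, format = "BED"),
                 error = function(e)
                   stop("malformed BED file '", bed, "': ",
                        conditionMessage(e), call. = FALSE))
  if (length(gr) == 0L) stop("no intervals in BED file: ", bed)
  if (!is(genome, "DNAStringSet"))
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  missing <- setdiff(unique(chroms), names(genome))
  if (length(missing))
    stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "))
  ids <- gr$name
  if (is.null(ids) || anyNA(ids) || any(ids %in% c("", ".")))
    ids <- sprintf("bed_%05d", seq_along(gr))
  strands <- as.character(GenomicRanges::strand(gr))
  strands[strands == "*"] <- "+"
  out <- character(length(gr))
  truncated <- 0L
  for (i in seq_along(gr)) {
    contig <- genome[[chroms[i]]]
    clen <- length(contig)
    s <- GenomicRanges::start(gr)[i]   # 1-based
    e <- GenomicRanges::end(gr)[i]
    if (e > clen || s < 1L)
      stop("interval ", ids[i], " outside contig ", chroms[i])
    if (strands[i] == "+") {
      fe <- min(clen, e + flank)
      if (fe < e + flank) truncated <- truncated + 1L
      out[i] <- as.character(Biostrings::subseq(contig, s, fe))
    } else {
      fs <- max(1L, s - flank)
      if (fs > s - flank) truncated <- truncated + 1L
      out[i] <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(contig, fs, e)))
    }
  }
  if (truncated > 0L)
    warning(truncated, " locus flank(s) truncated at a contig edge")
  gr2 <- gr
  names(gr2) <- ids
  AluLocusSet(setNames(out, ids), ranges = gr2)
}

#' Load Alu loci from a RepeatMasker .out annotation
#'
#' Parses the RepeatMasker `.out` dialect (3 header lines, then
#' whitespace-delimited columns), keeps rows whose repeat family matches
#' `family` (default "Alu"), converts the 1-based inclusive query
#' coordinates to the package's 0-based half-open convention, and maps
#' strand `C` to `-`. Unparseable rows are skipped with a warning giving
#' the count. Sequence is not attached; combine with a genome via
#' [loadLociFromBed()]-style extraction using the returned ranges.
#'
#' @param path RepeatMasker .out file.
#' @param family Regular expression matched against the repeat
#'   class/family and repeat name columns.
#' @return A [GenomicRanges::GRanges] with metadata columns
#'   `repeat_name` and `repeat_class`.
#' @export
loadRepeatMaskerOut <- function(path, family = "Alu") {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) > 3L) lines <- lines[-(1:3)] else lines <- character(0)
  lines <- lines[nzchar(trimws(lines))]
  keep <- list()
  skipped <- 0L
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    ok <- length(f) >= 11L &&
      !is.na(suppressWarnings(as.integer(f[6]))) &&
      !is.na(suppressWarnings(as.integer(f[7]))) &&
      f[9] %in% c("+", "C")
    if (!ok) { skipped <- skipped + 1L; next }
    if (!grepl(family, f[11]) && !grepl(family, f[10])) next
    keep[[length(keep) + 1L]] <- data.frame(
      chrom = f[5], start0 = as.integer(f[6]) - 1L, end = as.integer(f[7]),
      strand = if (f[9] == "C") "-" else "+",
      repeat_name = f[10], repeat_class = f[11], stringsAsFactors = FALSE)
  }
  if (skipped > 0L)
    warning(skipped, " unparseable RepeatMasker row(s) skipped")
  if (length(keep) == 0L)
    return(GenomicRanges::GRanges(repeat_name = character(0),
                                  repeat_class = character(0)))
  df <- do.call(rbind, keep)
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start0 + 1L, end = df$end),
    strand = df$strand,
    repeat_name = df$repeat_name, repeat_class = df$repeat_class)
}
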