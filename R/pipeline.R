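#' Run the full classification and scoring pipeline
#'
#' End-to-end orchestration: load loci (FASTA, BED + genome, or an
#' in-memory [AluLocusSet-class]), merge duplicates across cell lines,
#' extract features, apply the structural filters, compute key bins and
#' ERP scores, and assemble the cohort statistics. When `outDir` is
#' given, writes a per-locus feature/score TSV, a reject log with reason
#' codes, a JSON stats block and a human-readable summary; all outputs
#' echo the configuration in `#`-prefixed header lines and carry no
#' timestamps, so identical inputs and configuration give byte-identical
#' files.
#'
#' @param input Path to a FASTA or BED file, an [AluLocusSet-class], or
#'   a named list of `AluLocusSet` (one per cell line; duplicates are
#'   merged by reciprocal coordinate overlap, see [findDuplicates()]).
#' @param mode `"fasta"`, `"bed"` or `"loci"` (auto-detected for
#'   in-memory input).
#' @param genome Genome FASTA path or `DNAStringSet` (BED mode only).
#' @param library A [ConsensusLibrary-class]. The bundled
#'   [syntheticConsensusLibrary()] is for simulation and testing; supply
#'   a real consensus library for genomic work.
#' @param scoreTables A [ScoreTables-class] or a config-file path for
#'   [loadScoreTables()].
#' @param cfg A [keyConfig()].
#' @param flank Downstream flank / unique-region window (default 300).
#' @param thresholds ERP reporting thresholds (default 0.10/0.20/0.50).
#' @param bBoxRequired Genome-wide B-box gate (default `FALSE`).
#' @param genomicFractions For enrichment, see [aluGenomicFractions()].
#' @param outDir Output directory, or `NULL` for in-memory results only.
#' @param seed Seed echoed into output headers (the pipeline itself is
#'   deterministic; the seed matters when the input was simulated).
#' @param verbose Log per-stage counts to stderr.
#' @return (Invisibly) list: `loci`, `features`, `scored`, `rejects`,
#'   `stats` (subfamily table, Fisher OR/p, threshold counts, ERP
#'   medians, duplicate accounting), `files`.
#' @examples
#' co <- generateCohort(20, seed = 3)
#' res <- runAluPipeline(co$loci, verbose = FALSE)
#' res$stats$threshold_counts
#' @export
runAluPipeline <- function(input, mode = c("auto", "fasta", "bed", "loci"),
                           genome = NULL,
                           library = syntheticConsensusLibrary(),
                           scoreTables = defaultScoreTables(),
                           cfg = keyConfig(), flank = 300L,
                           thresholds = c(0.10, 0.20, 0.50),
                           bBoxRequired = FALSE,
                           genomicFractions = aluGenomicFractions(),
                           outDir = NULL, seed = NULL, verbose = TRUE) {
  mode <- match.arg(mode)
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(scoreTables))
    scoreTables <- loadScoreTables(scoreTables)
  dup <- NULL
  if (is(input, "AluLocusSet")) {
    loci <- input
  } else if (is.list(input) && all(vapply(input, is, TRUE, "AluLocusSet"))) {
    dup <- findDuplicates(input)
    loci <- dup$loci
    say("stage load: %d entries in %d cell-line lists merged to %d loci (%d multi-line, %.1f%%)",
        sum(vapply(input, length, 1L)), length(input), length(loci),
        dup$n_multi, dup$pct_multi)
  } else if (is.character(input)) {
    if (mode == "auto")
      mode <- if (grepl("\\.bed$", input, ignore.case = TRUE)) "bed" else "fasta"
    loci <- switch(mode,
      fasta = loadLociFromFasta(input),
      bed = {
        if (is.null(genome)) stop("BED mode requires a genome")
        loadLociFromBed(input, genome, flank = flank)
      },
      stop("unsupported input mode: ", mode))
  } else stop("unsupported input")
  say("stage load: %d loci", length(loci))

  features <- extractFeatures(loci, library, flank = flank,
                              bboxMotif = "GWTCRANNC")
  rejects <- features[!features$structure_ok, , drop = FALSE]
  say("stage filter: %d retained, %d rejected (%s)",
      sum(features$structure_ok), nrow(rejects),
      if (nrow(rejects)) paste(names(table(rejects$reject_reason)),
                               table(rejects$reject_reason),
                               sep = "=", collapse = ", ") else "none")

  scored <- scoreCohort(features, scoreTables, cfg,
                        thresholds = thresholds,
                        bBoxRequired = bBoxRequired)
  say("stage score: %d loci scored", nrow(scored))

  stats <- list()
  if (nrow(scored) > 0L) {
    sfTab <- subfamilySummary(scored$age_class, genomicFractions)
    ct <- buildAgeContingency(sfTab, genomicFractions)
    fe <- fisherExact(ct)
    stats <- list(
      n_input = length(loci),
      n_scored = nrow(scored),
      n_rejected = nrow(rejects),
      subfamily_table = sfTab,
      contingency = ct,
      odds_ratio = fe$odds_ratio,
      fisher_p = fe$p_value,
      threshold_counts = thresholdCounts(scored$erp, thresholds),
      erp_median = stats::median(scored$erp),
      n_potentially_active = sum(scored$potentially_active))
    if (!is.null(dup)) {
      stats$n_multi <- dup$n_multi
      stats$pct_multi <- dup$pct_multi
    }
  }

  files <- character(0)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", outDir)
    hdr <- c(
      "# AluERP pipeline report",
      sprintf("# seed: %s", if (is.null(seed)) "NA" else seed),
      sprintf("# flank window: %d", flank),
      sprintf("# key thresholds: divergence bins %s; tail >= %g; unique <= %g; disruption <= %g%%",
              paste(cfg@divergenceBins, collapse = "/"), cfg@aTailMin,
              cfg@uniqueMax, cfg@disruptionMax),
      sprintf("# ERP thresholds: %s", paste(thresholds, collapse = ", ")),
      sprintf("# ERP floor: %g", scoreTables@floor),
      sprintf("# B-box required: %s", bBoxRequired),
      "# divergence metric: 100 * (mismatches + indel events) / aligned consensus columns; body only, indel run = one event")
    writeTsv <- function(df, path) {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(hdr, con)
      utils::write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      path
    }
    files["scored"] <- writeTsv(scored, file.path(outDir, "loci_scored.tsv"))
    files["rejects"] <- writeTsv(
      rejects[, c("locus_id", "subfamily", "divergence_pct", "reject_reason")],
      file.path(outDir, "rejects.tsv"))
    statsOut <- stats
    statsOut$subfamily_table <- cbind(group = rownames(stats$subfamily_table),
                                      stats$subfamily_table)
    statsOut$contingency <- as.vector(stats$contingency)
    files["stats"] <- file.path(outDir, "stats.json")
    jsonlite::write_json(statsOut, files[["stats"]], auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", pretty = TRUE)
    files["summary"] <- file.path(outDir, "summary.txt")
    summ <- c(hdr,
              sprintf("loci in: %d; scored: %d; rejected: %d",
                      length(loci), nrow(scored), nrow(rejects)),
              if (!is.null(dup))
                sprintf("multi-cell-line loci: %d of %d (%.1f%%)",
                        dup$n_multi, length(loci), dup$pct_multi),
              sprintf("potentially active (key): %s",
                      if (nrow(scored)) sum(scored$potentially_active) else 0),
              sprintf("ERP >= %g: %s", thresholds,
                      if (nrow(scored)) thresholdCounts(scored$erp, thresholds)
                      else rep(0L, length(thresholds))))
    writeLines(summ, files[["summary"]])
  }
  invisible(list(loci = loci, features = features, scored = scored,
                 rejects = rejects, stats = stats, files = files))
}

#' Simulate a cohort and write its fixture bundle
#'
#' Thin wrapper over [generateCohort()] for scripted use: simulates `n`
#' loci (optionally with duplicates planted across cell lines) and
#' writes FASTA / BED / truth-table fixtures.
#'
#' @inheritParams generateCohort
#' @return See [generateCohort()].
#' @export
simulateAluCohort <- function(n, seed, dir, nShared = 0L, ...) {
  generateCohort(n, seed = seed, nShared = nShared, dir = dir, ...)
}
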