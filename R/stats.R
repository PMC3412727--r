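#' Genomic age-class fractions of full-length Alu elements
#'
#' Published fractions of the 530,850 full-length genomic Alus per age
#' class: S+J 84.5%, the Y lineage 15.5% (of which Ya5 0.63% and
#' Yb8 0.42%). The `Y` entry is inclusive of Ya5/Yb8 on the genomic
#' side, the convention used by the subfamily-distribution table this
#' mirrors.
#'
#' @return Named numeric vector of fractions plus
#'   `attr(, "total_full_alus")`.
#' @export
aluGenomicFractions <- function() {
  out <- c(`S+J` = 0.845, Y = 0.155, Ya5 = 0.0063, Yb8 = 0.0042)
  attr(out, "total_full_alus") <- 530850L
  out
}

.ageGroupCounts <- function(ageClass) {
  c(`S+J` = sum(ageClass %in% c("S", "J")),
    Y = sum(ageClass == "Y"),
    Ya5 = sum(ageClass == "Ya5"),
    Yb8 = sum(ageClass == "Yb8"))
}

#' Subfamily distribution and copy-number-normalized enrichment
#'
#' Summarizes a scored cohort per age-class group (`S+J`, `Y` exclusive
#' of Ya5/Yb8, `Ya5`, `Yb8`): bound count, bound fraction (one-decimal
#' percent) and enrichment = (bound fraction) / (genomic fraction),
#' reported to one decimal. A group with genomic fraction 0 gets an
#' undefined (`NA`) enrichment, never infinity.
#'
#' @param ageClass Character vector of per-locus age classes (`J`, `S`,
#'   `Y`, `Ya5`, `Yb8`), e.g. the `age_class` column of a scored cohort,
#'   or a named count vector with names `S+J`, `Y`, `Ya5`, `Yb8`.
#' @param genomicFractions Named fractions as in [aluGenomicFractions()].
#' @return data.frame with rows `S+J`, `Y`, `Ya5`, `Yb8` and columns
#'   `genomic_pct`, `bound_count`, `bound_pct`, `enrichment`.
#' @examples
#' subfamilySummary(c(`S+J` = 143, Y = 16, Ya5 = 2, Yb8 = 1))
#' @export
subfamilySummary <- function(ageClass,
                             genomicFractions = aluGenomicFractions()) {
  counts <- if (is.numeric(ageClass)) {
    stopifnot(all(c("S+J", "Y", "Ya5", "Yb8") %in% names(ageClass)))
    ageClass[c("S+J", "Y", "Ya5", "Yb8")]
  } else .ageGroupCounts(ageClass)
  N <- sum(counts)
  gf <- genomicFractions[names(counts)]
  enr <- ifelse(gf > 0, (counts / N) / gf, NA_real_)
  data.frame(
    row.names = names(counts),
    genomic_pct = 100 * unname(gf),
    bound_count = as.integer(unname(counts)),
    bound_pct = .pct1(100 * unname(counts) / N),
    enrichment = .pct1(unname(enr)))
}

#' Build the 2x2 age-group contingency table
#'
#' Rows are age groups (older S+J vs the Y lineage), columns bound / not
#' bound by pol III factors. Under the default `"exclusive"` grouping
#' the bound Y count excludes Ya5/Yb8 while the genomic Y total is
#' inclusive of them (the convention of the published subfamily table,
#' which reproduces its odds ratio); `"inclusive"` counts the whole Y
#' lineage on both sides.
#'
#' @param summary Output of [subfamilySummary()], or a named count
#'   vector (`S+J`, `Y`, `Ya5`, `Yb8`) of bound loci.
#' @param genomicFractions Named fractions as in [aluGenomicFractions()].
#' @param totalAlus Total full-length genomic Alus (default 530,850).
#' @param grouping `"exclusive"` or `"inclusive"`.
#' @return 2x2 integer matrix with dimnames
#'   `list(c("S+J","Y"), c("bound","not_bound"))`.
#' @export
buildAgeContingency <- function(summary,
                                genomicFractions = aluGenomicFractions(),
                                totalAlus = attr(aluGenomicFractions(),
                                                 "total_full_alus"),
                                grouping = c("exclusive", "inclusive")) {
  grouping <- match.arg(grouping)
  counts <- if (is.data.frame(summary)) {
    setNames(summary$bound_count, rownames(summary))
  } else summary
  a <- counts[["S+J"]]
  cc <- if (grouping == "exclusive") counts[["Y"]]
        else counts[["Y"]] + counts[["Ya5"]] + counts[["Yb8"]]
  b <- round(genomicFractions[["S+J"]] * totalAlus) - a
  d <- round(genomicFractions[["Y"]] * totalAlus) - cc
  m <- matrix(as.integer(c(a, cc, b, d)), nrow = 2,
              dimnames = list(c("S+J", "Y"), c("bound", "not_bound")))
  m
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided point-probability method: with margins fixed, the p-value
#' sums the hypergeometric point probabilities of all tables at most as
#' probable as the observed one. The odds ratio is the sample odds ratio
#' `(a*d)/(b*c)` (reported `Inf` when `b*c = 0`), not the conditional
#' MLE.
#'
#' @param m 2x2 matrix of non-negative counts.
#' @return List: `odds_ratio`, `p_value`.
#' @examples
#' fisherExact(matrix(c(3, 1, 1, 3), 2))  # p = 34/70
#' @export
fisherExact <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == 2L), all(m >= 0))
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  if (sum(m) == 0L) stop("at least one margin must be positive")
  orat <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * cc)
  m1 <- a + b          # row 1 total
  m2 <- cc + d         # row 2 total
  n1 <- a + cc         # col 1 total
  support <- max(0L, n1 - m2):min(m1, n1)
  dens <- stats::dhyper(support, m1, m2, n1)
  dObs <- stats::dhyper(a, m1, m2, n1)
  p <- sum(dens[dens <= dObs * (1 + 1e-7)])
  list(odds_ratio = unname(orat), p_value = min(1, p))
}

#' Wilcoxon rank-sum test with midrank ties
#'
#' Rank-sum (Mann-Whitney) test: ranks are midranks over the pooled
#' sample. When `n_x + n_y <= exactMax` (default 12) the two-sided
#' p-value is computed by exact enumeration of all rank assignments
#' (valid under ties); otherwise by normal approximation with tie
#' correction and continuity correction. The statistic is the
#' Mann-Whitney U of `x`.
#'
#' @param x,y Non-empty numeric samples.
#' @param exactMax Largest pooled size for the exact branch.
#' @return List: `statistic` (U), `p_value`, `method`.
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
wilcoxonRankSum <- function(x, y, exactMax = 12L) {
  stopifnot(length(x) > 0L, length(y) > 0L)
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  U <- W - m * (m + 1) / 2
  mu <- m * (N + 1) / 2
  if (N <= exactMax) {
    combs <- utils::combn(N, m)
    Ws <- colSums(matrix(r[combs], nrow = m))
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
    return(list(statistic = U, p_value = p, method = "exact enumeration"))
  }
  ties <- table(r)
  sigma2 <- (m * n / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0)
    return(list(statistic = U, p_value = 1,
                method = "normal approximation"))
  z <- W - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  list(statistic = U, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation")
}

#' Merge loci identified in multiple cell lines
#'
#' Loci are merged when their genomic intervals overlap reciprocally by
#' at least `minOverlap` on the same strand (or, for coordinate-free
#' FASTA-mode sets, when their identifiers match exactly). Each merged
#' locus is represented once, carrying the union of its source cell
#' lines; the function reports how many merged loci were seen in two or
#' more cell lines.
#'
#' @param cohorts Named list mapping cell line to [AluLocusSet-class],
#'   or a single `AluLocusSet` whose `cellLines` are already populated.
#' @param minOverlap Reciprocal overlap fraction (default 0.9).
#' @return List: `loci` (merged [AluLocusSet-class]), `n_multi`,
#'   `pct_multi` (one decimal).
#' @export
findDuplicates <- function(cohorts, minOverlap = 0.9) {
  if (is(cohorts, "AluLocusSet")) {
    sets <- list(cohorts)
  } else {
    stopifnot(is.list(cohorts), length(cohorts) > 0L)
    sets <- lapply(names(cohorts), function(cl) {
      s <- cohorts[[cl]]
      empty <- lengths(cellLines(s)) == 0L
      if (any(empty)) {
        newCl <- as.list(cellLines(s))
        newCl[empty] <- list(cl)
        s@cellLines <- IRanges::CharacterList(newCl)
      }
      s
    })
  }
  ids <- unlist(lapply(sets, lociIds))
  seqs <- unlist(lapply(sets, function(s) as.character(lociSeqs(s))))
  cls <- do.call(c, lapply(sets, function(s) as.list(cellLines(s))))
  haveRanges <- all(vapply(sets, function(s) length(lociRanges(s)) > 0L,
                           TRUE))
  nTot <- length(ids)
  parent <- seq_len(nTot)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      r <- min(ri, rj)
      parent[ri] <<- r
      parent[rj] <<- r
    }
  }
  if (haveRanges) {
    gr <- do.call(c, lapply(sets, function(s) {
      g <- lociRanges(s); names(g) <- NULL; GenomicRanges::granges(g)
    }))
    hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = FALSE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    keep <- qh < sh
    qh <- qh[keep]; sh <- sh[keep]
    if (length(qh)) {
      ov <- GenomicRanges::width(GenomicRanges::pintersect(gr[qh], gr[sh]))
      rec <- ov / GenomicRanges::width(gr[qh]) >= minOverlap &
        ov / GenomicRanges::width(gr[sh]) >= minOverlap
      for (k in which(rec)) union2(qh[k], sh[k])
    }
  } else {
    for (grp in split(seq_len(nTot), ids))
      if (length(grp) > 1L)
        for (k in grp[-1L]) union2(grp[1L], k)
  }
  roots <- vapply(seq_len(nTot), find, 1L)
  groups <- split(seq_len(nTot), roots)
  reps <- vapply(groups, function(g) g[[1L]], 1L)
  mergedCl <- lapply(groups, function(g) sort(unique(unlist(cls[g]))))
  merged <- AluLocusSet(
    setNames(seqs[reps], ids[reps]),
    ranges = if (haveRanges) {
      gAll <- do.call(c, lapply(sets, function(s) {
        g <- lociRanges(s); names(g) <- NULL; g
      }))
      g <- gAll[reps]; names(g) <- ids[reps]; g
    } else NULL,
    cellLines = mergedCl)
  nMulti <- sum(lengths(mergedCl) >= 2L)
  list(loci = merged, n_multi = nMulti,
       pct_multi = .pct1(100 * nMulti / length(merged)))
}

#' Counts of loci meeting ERP thresholds
#'
#' @param erp Numeric ERP scores.
#' @param thresholds ERP thresholds (default `c(0.10, 0.20, 0.50)`).
#' @return Named integer vector: count of loci with `erp >= t`
#'   (inclusive) for each threshold; non-increasing across ascending
#'   thresholds.
#' @export
thresholdCounts <- function(erp, thresholds = c(0.10, 0.20, 0.50)) {
  vapply(setNames(thresholds, sprintf(">=%g", thresholds)),
         function(t) sum(erp >= t, na.rm = TRUE), 1L)
}
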