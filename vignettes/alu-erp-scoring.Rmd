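---
title: "Scoring the retrotransposition potential of Alu loci"
author: "AluERP package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the retrotransposition potential of Alu loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AluERP)
```

## The biological problem

Alu elements are ~300-bp primate SINEs with a dimeric structure: two
related monomer arms joined by an A-rich linker, ending in an A-tail.
They are mobilized in trans by the L1 machinery, and of the million-plus
genomic copies only a handful of "source" loci generate new insertions.
Transcription by RNA polymerase III is a precondition — the pol III
transcript runs from the element start, through the A-tail, across the
downstream "unique" genomic sequence, up to the first pol III terminator
(a run of four or more thymidines) — but transcription alone is not
sufficient. Four sequence features measurably affect the
retrotransposition efficiency of a transcribed locus:

1. **Divergence from the subfamily consensus** — accumulated mutations
   reduce activity; elements more than 10% diverged are treated as
   retrotranspositionally inactive.
2. **A-tail length** — a minimum length is required; 20 bp is the
   threshold for potential activity.
3. **Unique-region length** — sequence transcribed between the A-tail
   and the terminator reduces efficiency; 20 bp or less scores positive.
4. **A-tail homogeneity** — non-A interruptions reduce efficiency; 10%
   disruption or less scores positive.

The package implements the full analysis around these features: locus
ingestion, structural filtering, feature extraction, a dichotomous
classification key, a continuous estimated retrotransposition potential
(ERP) score, and the cohort-level statistics used to characterize sets
of pol III-bound loci.

## The data model and the processing stages

Loci enter as an `AluLocusSet` (element-sense sequence = body plus up to
300 bp of 3' flank, optional genomic coordinates, per-locus cell-line
labels), built from FASTA (`loadLociFromFasta()`), from BED intervals
plus a genome (`loadLociFromBed()`, strand-aware so that the A-tail is
always downstream), or from a RepeatMasker annotation
(`loadRepeatMaskerOut()`; coordinates are converted to the package-wide
0-based half-open convention on read). The genome assembly behind
coordinates is always the user's input; nothing is assumed.

`extractFeatures()` runs per locus:

- **Body location** (`locateBody()`): a pairwise alignment against every
  consensus in a `ConsensusLibrary`, global in the consensus and local
  in the locus (match +1, mismatch −1, gap open 5, gap extend 1; all
  config-exposed). The best-scoring consensus assigns the subfamily,
  with ties broken by lexicographic name. Divergence is
  `100 × (mismatches + indel events) / aligned consensus columns`, where
  a contiguous gap run counts as one event — body-only (tail and flank
  excluded), in line with common repeat-annotation practice. CpG
  positions receive no special treatment; the metric is stated in every
  report header. N bases count as mismatches, and loci with more than
  10% N are rejected outright.
- **Structural filter** (`structuralFilter()`): loci that do not fit the
  standard dimeric structure are removed — FLAM/FRAM-like monomers
  (exactly one consensus half covered at ≥50% identity), partial
  elements (fewer than 200 consensus bases covered), and elements with
  an internal pol III terminator, which would yield truncated
  transcripts. Identity coverage (consensus positions aligned to an
  identical base) rather than raw alignment extent is used because a
  global-in-consensus alignment always "covers" the consensus; identity
  is what distinguishes a homologous arm from the A-tail absorbing the
  other arm's columns. Whether the 200-base cutoff matches any
  particular published filter is unknowable from printed numbers alone;
  it is config-exposed.
- **A-tail** (`measureATail()`): scan right from the body end, stopping
  at the first of three consecutive non-A bases, a terminator, or the
  sequence end, then trim trailing non-A. The stop-and-trim rule is this
  package's operationalization — tail boundaries have no universal
  definition — chosen so that homogeneous and mildly heterogeneous tails
  are measurable and exactly recoverable on synthetic data. The tail
  never crosses a terminator start.
- **Unique region** (`measureUniqueRegion()`): distance from the tail
  end to the first terminator within a 300-bp window, capped at the
  window if none is found.
- **B box** (`hasBBox()`): the degenerate internal-promoter motif
  (IUPAC `GWTCRANNC` by default) must start within consensus offsets
  60–90, mapped through the alignment into locus coordinates. Motif and
  window are config-exposed; the default window brackets the canonical
  B-box position of the left monomer.

## The key and the ERP score

`applyKey()` applies the dichotomous key with literal boundary
conventions: divergence bins `<5%`, `5–10%` (inclusive), `>10%`
(inactive); tail pass at `>= 20` bases; unique pass at `<= 20` bases;
disruption pass at `<= 10%`. A locus is *potentially active* iff
divergence is at most 10% and the other three criteria pass.

`erpScore()` computes the continuous score as the product of four
per-feature impact factors R in `[0, 1]`:

$$\mathrm{ERP} = \max\bigl(\mathrm{floor},\;
R_{\mathrm{div}}(d) \times R_{\mathrm{tail}}(L) \times
R_{\mathrm{uniq}}(u) \times R_{\mathrm{disr}}(p)\bigr)$$

Multiplicative composition is forced by the score's anchors: an ideal
element scores exactly 1.00, realistic imperfect elements score values
like 0.20 or 0.04, and cohort medians sit near 10⁻⁶ — consistent with
products of sub-unit factors, not sums. The default tables
(`defaultScoreTables()`) are explicit, documented stand-ins: piecewise
linear with factor 1.0 at the reference value (consensus-identical body,
50-base pure tail, 0-base unique region, homogeneous tail), 0.5 at the
corresponding key threshold, and the floor (default 10⁻⁶, matching the
order of magnitude of old-subfamily cohort medians) beyond twice the
threshold. `loadScoreTables()` exists precisely so that empirically
measured tables can replace any subset of the four verbatim; the loader
validates range and monotonicity and reports offending rows. For
genome-wide scans a B-box gate (`bBoxRequired`) restricts scoring to
B-box-containing loci; the gate is applied before scoring.

ERP deliberately ignores transcription status: it ranks sequence
competence, not expression.

## Cohort statistics

- `subfamilySummary()` tabulates bound counts per age-class group and
  normalizes by the genomic copy-number fractions of full-length Alus
  (`aluGenomicFractions()`: S+J 84.5%, Y lineage 15.5%, Ya5 0.63%,
  Yb8 0.42% of 530,850). Conventions mirror the published table: the Y
  row is exclusive of Ya5/Yb8 on the bound side and inclusive on the
  genomic side; enrichment and percentages are reported to one decimal.
- `buildAgeContingency()` + `fisherExact()` test the age-class
  association. The two-sided p-value uses the point-probability method
  (summing hypergeometric probabilities at most that of the observed
  table) and the odds ratio is the sample `ad/bc` — with the default
  grouping this reproduces the published odds ratio of 1.6 from the
  printed table. The grouping is config-exposed because the printed
  numbers admit an inclusive alternative.
- `wilcoxonRankSum()` compares ERP distributions with midrank ties,
  exact enumeration for pooled sizes up to 12 and a tie- and
  continuity-corrected normal approximation above.
- `findDuplicates()` merges loci identified in several cell lines:
  ≥90% reciprocal coordinate overlap on the same strand (exact id match
  for coordinate-free sets). The overlap rule is this package's
  operationalization of "identified in at least two cell lines"; each
  merged locus is counted once.
- `thresholdCounts()` reports inclusive counts at ERP ≥ 0.10 / 0.20 /
  0.50.

No multiple-testing correction is applied across subfamilies, matching
the analysis the statistics mirror.

## The synthetic-data generator

`generateLocus()` builds `mutated body + A-tail + unique region +
T-run terminator` from a `locusSpec()`, and `generateCohort()` wraps it
into cohorts with synthetic coordinates, cell-line assignments, planted
cross-cell-line duplicates, and FASTA/BED/TSV fixtures. The default
cohort conditions mirror the bound-locus setting the statistics are
designed for: subfamily proportions 88.4% S+J (split 30/58.4 between J
and S), 9.8% Y, 1.2% Ya5, 0.6% Yb8; divergence drawn per age class
(J: 8–16%, S: 5–12%, Y: 1–6%, Ya5/Yb8: 0–3%), tails of 5–60 bases,
disruption 0–20%, unique regions of 0–80 bases, terminators of 4–8 Ts.
Where no published value exists (the tail/unique/disruption ranges),
the defaults are one-time choices of plausible magnitudes for pol
III-bound loci, not fitted quantities.

The generator is engineered so ground truth is *exactly* recoverable:

- The bundled 282-bp dimeric test consensus (B-box embedded at offset
  72, A5-TACA-A6 linker, last two bases non-A) contains no TTT run and
  no `TT[ACG]TT` motif, so no single mutation can create a TTTT
  terminator inside the body.
- Mutations (10% single-base indels, the rest substitutions) are placed
  pairwise non-adjacent, never introduce T, and never touch the final
  ten body bases. The intact terminal block anchors the alignment at
  the body/tail junction — without it, equal-scoring alignment variants
  occasionally shift the recovered body end by one base. This is a
  deliberate deviation from placing mutations uniformly over the whole
  body, traded for an exact tail-length ground truth.
- Tail disruptions are isolated (never ≥2 consecutive non-A) and never
  terminal; the unique region opens with three C/G bases (all C/G if
  shorter than 3), carries only isolated, non-terminal Ts, and is
  followed by the terminator run.

What the generator does *not* emulate: transition/transversion bias,
CpG hypermutability, tandem expansions of the A-tail, nested or
truncated insertions, and genomic flank composition. Passing the
recovery tests therefore demonstrates correctness of the measurement
rules and alignment bookkeeping, not robustness to every mutational
process shaping real Alus.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open internally; BED is native,
  RepeatMasker is converted on read.
- Alignment ties between consensuses break by higher score, then
  lexicographic subfamily name.
- A divergence so high that the mutated body would collapse below 50
  bases raises a "degenerate body" error in the generator.
- An empty tail has disruption 0 by definition; a group with genomic
  fraction 0 has undefined (NA), not infinite, enrichment; an odds
  ratio with an empty denominator is reported as `Inf`.
- Reports round percentages and enrichments to one decimal; ERP is
  written at full precision.
- Pipeline outputs carry no timestamps and echo the full configuration,
  so byte-identical reruns are a testable contract.

## Problem sizes used in the test suite

The suite validates feature recovery on a 500-locus synthetic cohort,
Fisher's exact test against exhaustive hypergeometric enumeration for
every 2×2 table with N ≤ 40, ERP monotonicity on 10,000 random feature
vectors, terminator scanning against a brute-force oracle on 10,000
random strings, and end-to-end determinism on multi-cell-line cohorts
with planted duplicates. These sizes keep the whole suite under a
couple of minutes while leaving the properties statistically sharp.

## A worked example

```{r example}
co <- generateCohort(162, seed = 42, nShared = 24)
res <- runAluPipeline(co$byCellLine, verbose = FALSE)
res$stats$subfamily_table
res$stats$n_multi
res$stats$threshold_counts
```

## Known limitations

- The default score tables are stand-ins with the correct anchors and
  shapes, not the empirically measured factors; absolute ERP values
  under the defaults should be read as calibrated ranks, and users with
  measured tables should load them.
- Divergence is a single uniform-cost metric; no CpG adjustment or
  age-calibrated distance is attempted.
- The B-box scan is a motif match in a window, not a promoter-strength
  model; A-box scoring is out of scope.
- ERP says nothing about whether a locus is actually transcribed.
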