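Package: AluERP
Title: Retrotransposition Potential Scoring of RNA Polymerase III Bound Alu Elements
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extracts retrotransposition-relevant sequence features from Alu
    SINE loci (subfamily assignment and percent divergence by pairwise
    alignment to consensus, poly-A tail length and disruption, unique 3'
    region length up to the first RNA polymerase III terminator, B-box
    presence), applies a dichotomous classification key, computes a
    continuous estimated retrotransposition potential (ERP) score from
    per-feature multiplicative lookup tables, and provides cohort-level
    statistics (subfamily enrichment against genomic copy numbers, Fisher's
    exact test, Wilcoxon rank-sum comparisons, duplicate-locus accounting
    across cell lines). Includes a synthetic Alu-like locus generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, Annotation, Transcription
RoxygenNote: 7.3.3
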