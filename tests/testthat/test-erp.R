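feat <- function(div, tail, uniq, disr, ok = TRUE, bbox = TRUE) {
  S4Vectors::DataFrame(divergence_pct = div, a_tail_len = as.integer(tail),
                       unique_len = as.integer(uniq),
                       a_tail_disruption_pct = disr,
                       structure_ok = ok, has_b_box = bbox)
}

test_that("the dichotomous key applies the quoted boundary conventions", {
  k <- applyKey(feat(3, 25, 10, 4))
  expect_identical(k$divergence_bin, "lt5")
  expect_true(all(k$a_tail_pass, k$unique_pass, k$disruption_pass,
                  k$potentially_active))
  # over 10% divergence: inactive regardless of the rest
  k <- applyKey(feat(12, 50, 0, 0))
  expect_identical(k$divergence_bin, "gt10")
  expect_false(k$potentially_active)
  # tail of 19 fails (pass is >= 20, inclusive at 20)
  expect_false(applyKey(feat(3, 19, 10, 4))$a_tail_pass)
  expect_true(applyKey(feat(3, 20, 10, 4))$a_tail_pass)
  # inclusive boundaries: d = 10, unique = 20, disruption = 10 all pass
  k <- applyKey(feat(10, 20, 20, 10))
  expect_identical(k$divergence_bin, "5to10")
  expect_true(k$potentially_active)
  # rejected loci have no key result
  expect_error(applyKey(feat(3, 25, 10, 4, ok = FALSE)), "filtered locus")
})

test_that("ERP is exactly 1.00 at the reference features", {
  expect_identical(erpScore(feat(0, 50, 0, 0)), 1)
})

test_that("ERP is the product of the four R factors with a floor", {
  tabs <- defaultScoreTables()
  # default-table factors: div 10 -> 0.5, tail 38 -> 0.8, unique 20 -> 0.5,
  # disruption 0 -> 1.0; product 0.20
  expect_equal(erpScore(feat(10, 38, 20, 0), tabs), 0.5 * 0.8 * 0.5 * 1.0,
               tolerance = 1e-12)
  # far beyond the tables: clamped at the floor
  expect_identical(erpScore(feat(25, 50, 0, 0), tabs), tabs@floor)
  expect_identical(erpScore(feat(0, 50, 500, 0), tabs), tabs@floor)
  expect_error(erpScore(feat(0, 50, 0, 0, ok = FALSE)), "filtered locus")
  # genome-wide B-box gate
  expect_error(erpScore(feat(0, 50, 0, 0, bbox = FALSE), bBoxRequired = TRUE),
               "B-box")
})

test_that("score-table configs load, validate and partially override", {
  expect_silent(validObject(defaultScoreTables()))
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "tables.tsv")
  writeLines(c("feature\tvalue\tR",
               "a_tail\t0\t0",
               "a_tail\t30\t1"), cfg)
  tabs <- loadScoreTables(cfg)
  expect_equal(tabs@aTail$value, c(0, 30))
  expect_identical(tabs@divergence, defaultScoreTables()@divergence)
  expect_equal(erpScore(feat(0, 30, 0, 0), tabs), 1)
  # out-of-range R
  writeLines(c("feature\tvalue\tR", "unique\t0\t1.3", "unique\t10\t0"), cfg)
  expect_error(loadScoreTables(cfg), "outside \\[0,1\\]")
  # non-monotone in the feature's direction, offending row reported
  writeLines(c("feature\tvalue\tR",
               "divergence\t0\t0.2", "divergence\t5\t0.9"), cfg)
  expect_error(loadScoreTables(cfg), "non-increasing")
  # unknown feature name
  writeLines(c("feature\tvalue\tR", "wibble\t0\t1"), cfg)
  expect_error(loadScoreTables(cfg), "unknown feature")
})

test_that("ERP lies in [floor, 1] and is 1 only at the reference", {
  set.seed(808)
  n <- 2000
  f <- feat(runif(n, 0, 30), sample(0:80, n, TRUE), sample(0:100, n, TRUE),
            runif(n, 0, 40))
  e <- erpScore(f)
  expect_true(all(e >= defaultScoreTables()@floor & e <= 1))
  atRef <- f$divergence_pct == 0 & f$a_tail_len >= 50 &
    f$unique_len == 0 & f$a_tail_disruption_pct == 0
  expect_identical(e == 1, atRef)
})

test_that("ERP is monotone in each feature", {
  set.seed(909)
  n <- 10000
  div <- runif(n, 0, 25); tail <- sample(0:70, n, TRUE)
  uniq <- sample(0:60, n, TRUE); disr <- runif(n, 0, 30)
  e0 <- erpScore(feat(div, tail, uniq, disr))
  bump <- runif(n, 0.1, 5)
  expect_true(all(erpScore(feat(div + bump, tail, uniq, disr)) <= e0 + 1e-12))
  expect_true(all(erpScore(feat(div, tail, uniq + sample(1:20, n, TRUE),
                                disr)) <= e0 + 1e-12))
  expect_true(all(erpScore(feat(div, tail, uniq, disr + bump)) <= e0 + 1e-12))
  # tail length toward the reference (50) never decreases ERP
  grow <- pmin(50L, tail + sample(1:10, n, TRUE))
  longer <- pmax(tail, grow)
  expect_true(all(erpScore(feat(div, longer, uniq, disr)) >= e0 - 1e-12))
})

test_that("a potentially active locus outscores single-criterion failures", {
  base <- feat(4, 30, 10, 5)
  e <- erpScore(base)
  expect_true(applyKey(base)$potentially_active)
  worse <- list(feat(12, 30, 10, 5), feat(4, 12, 10, 5),
                feat(4, 30, 30, 5), feat(4, 30, 10, 18))
  for (w in worse) expect_lte(erpScore(w), e)
})

test_that("threshold classification uses inclusive boundaries", {
  expect_identical(erpThresholdClass(c(0.05, 0.1, 0.2, 0.5, 1)),
                   c("<0.1", ">=0.1", ">=0.2", ">=0.5", ">=0.5"))
})

test_that("scoreCohort drops rejected loci and applies the B-box gate", {
  lib <- syntheticConsensusLibrary()
  consY <- as.character(consensusSeqs(lib)[["AluY"]])
  good <- generateLocus(locusSpec(divergence = 0, aTailLen = 50,
                                  disruption = 0, uniqueLen = 0, seed = 1),
                        consY)
  mono <- generateLocus(locusSpec(structure = "monomeric", seed = 2), consY)
  loci <- AluLocusSet(c(good = good$sequence, mono = mono$sequence))
  f <- extractFeatures(loci, lib)
  sc <- scoreCohort(f)
  expect_identical(sc$locus_id, "good")
  expect_identical(sc$erp, 1)
  expect_identical(sc$threshold_class, ">=0.5")
  # with the gate on, a B-box-less locus is silently excluded, not an error
  f2 <- f
  f2$has_b_box[1] <- FALSE
  expect_identical(nrow(scoreCohort(f2, bBoxRequired = TRUE)), 0L)
})
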