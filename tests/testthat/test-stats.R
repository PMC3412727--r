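test_that("fisherExact matches hand-enumerated and symmetric cases", {
  r <- fisherExact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(r$p_value, 34 / 70, tolerance = 1e-12)
  expect_equal(r$odds_ratio, 9)
  r <- fisherExact(matrix(c(5, 5, 5, 5), 2))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)
  expect_identical(fisherExact(matrix(c(2, 3, 0, 4), 2,
                                      byrow = TRUE))$odds_ratio, Inf)
})

test_that("fisherExact equals the enumeration oracle for all tables N <= 16", {
  for (N in 1:16) {
    comp <- expand.grid(a = 0:N, b = 0:N, c = 0:N)
    comp <- comp[rowSums(comp) <= N, ]
    comp$d <- N - rowSums(comp)
    for (i in seq_len(nrow(comp))) {
      a <- comp$a[i]; b <- comp$b[i]; cc <- comp$c[i]; d <- comp$d[i]
      if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0)
        next
      p <- fisherExact(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p_value
      expect_equal(p, oracleFisherP(a, b, cc, d), tolerance = 1e-9,
                   label = sprintf("table (%d,%d,%d,%d)", a, b, cc, d))
    }
  }
})

test_that("fisherExact agrees with stats::fisher.test on random tables", {
  set.seed(1616)
  for (i in 1:500) {
    m <- matrix(rpois(4, 5), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisherExact(m)$p_value, fisher.test(m)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("the odds ratio is invariant under swapping both rows and columns", {
  set.seed(99)
  for (i in 1:50) {
    m <- matrix(rpois(4, 4) + 1, 2)
    sw <- m[2:1, 2:1]
    expect_equal(fisherExact(m)$odds_ratio, fisherExact(sw)$odds_ratio)
    expect_equal(fisherExact(m)$p_value, fisherExact(sw)$p_value)
  }
})

test_that("wilcoxonRankSum matches exact enumeration on small samples", {
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$p_value, 2 / 20)
  expect_equal(wilcoxonRankSum(c(1, 2), c(3, 4))$p_value, 2 / 6)
  expect_equal(wilcoxonRankSum(c(1, 1, 2, 2), c(1, 1, 2, 2))$p_value, 1)
  # cross-check against wilcox.test's exact branch on tie-free samples
  set.seed(321)
  for (i in 1:25) {
    x <- rnorm(5); y <- rnorm(6)
    expect_equal(wilcoxonRankSum(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-9)
  }
})

test_that("the normal approximation tracks the exact branch at n = 12 + 12", {
  set.seed(654)
  for (i in 1:20) {
    x <- rnorm(12); y <- rnorm(12, mean = runif(1, -1, 1))
    approx <- wilcoxonRankSum(x, y)$p_value       # N = 24: approximation
    exact <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_lt(abs(approx - exact), 0.02)
  }
})

test_that("subfamily summary reproduces the printed enrichment values", {
  s <- subfamilySummary(c(`S+J` = 143, Y = 16, Ya5 = 2, Yb8 = 1))
  expect_equal(s["Ya5", "enrichment"], 2.0)
  expect_equal(s["Yb8", "enrichment"], 1.5)
  expect_equal(s["S+J", "enrichment"], 1.0)
  expect_equal(s["Y", "enrichment"], 0.6)
  expect_equal(s["S+J", "bound_pct"], 88.3)
  # a class at half the cohort with genomic fraction one half: enrichment 1.0
  gf <- c(`S+J` = 0.5, Y = 0.5, Ya5 = 0.001, Yb8 = 0.001)
  s2 <- subfamilySummary(c(`S+J` = 81, Y = 81, Ya5 = 0, Yb8 = 0), gf)
  expect_equal(s2["S+J", "enrichment"], 1.0)
  # zero genomic fraction: undefined, not infinite
  gf0 <- c(`S+J` = 0.99, Y = 0.01, Ya5 = 0, Yb8 = 0)
  s3 <- subfamilySummary(c(`S+J` = 10, Y = 1, Ya5 = 1, Yb8 = 0), gf0)
  expect_true(is.na(s3["Ya5", "enrichment"]))
})

test_that("the reconstructed age-class table yields the published odds ratio", {
  ct <- buildAgeContingency(c(`S+J` = 143, Y = 16, Ya5 = 2, Yb8 = 1))
  expect_identical(as.vector(ct), c(143L, 16L, 448425L, 82266L))
  fe <- fisherExact(ct)
  expect_equal(round(fe$odds_ratio, 1), 1.6)
})

test_that("enrichment of a class sampled at its genomic fraction is ~1", {
  set.seed(5000)
  gf <- c(`S+J` = 0.845, Y = 0.1445, Ya5 = 0.0063, Yb8 = 0.0042)
  cls <- sample(names(gf), 5000, replace = TRUE, prob = gf)
  counts <- table(factor(cls, levels = names(gf)))
  s <- subfamilySummary(setNames(as.numeric(counts), names(gf)),
                        c(gf[c("S+J")], Y = 0.155, gf[c("Ya5", "Yb8")]))
  expect_equal(s["S+J", "enrichment"], 1.0, tolerance = 0.1)
})

test_that("duplicate detection merges by reciprocal overlap or id", {
  co <- generateCohort(162, seed = 6, nShared = 24)
  dup <- findDuplicates(co$byCellLine)
  expect_identical(length(dup$loci), 162L)
  expect_identical(dup$n_multi, 24L)
  expect_equal(dup$pct_multi, 14.8)
  # disjoint lists: no multi-line loci
  co2 <- generateCohort(20, seed = 7, nShared = 0)
  dup2 <- findDuplicates(co2$byCellLine)
  expect_identical(dup2$n_multi, 0L)
  expect_equal(dup2$pct_multi, 0)
  # a 1-base shift still overlaps reciprocally > 90%
  gr1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 400), "+")
  gr2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(102, 401), "+")
  names(gr1) <- "a"; names(gr2) <- "b"
  s1 <- AluLocusSet(c(a = "ACGT"), ranges = gr1)
  s2 <- AluLocusSet(c(b = "ACGT"), ranges = gr2)
  dup3 <- findDuplicates(list(HeLa = s1, K562 = s2))
  expect_identical(length(dup3$loci), 1L)
  expect_identical(dup3$n_multi, 1L)
  # opposite strands never merge
  GenomicRanges::strand(gr2) <- "-"
  s2 <- AluLocusSet(c(b = "ACGT"), ranges = gr2)
  expect_identical(findDuplicates(list(HeLa = s1, K562 = s2))$n_multi, 0L)
  # FASTA mode: exact id match
  f1 <- AluLocusSet(c(x = "AAAA", y = "CCCC"))
  f2 <- AluLocusSet(c(y = "CCCC", z = "GGGG"))
  dup4 <- findDuplicates(list(A = f1, B = f2))
  expect_identical(length(dup4$loci), 3L)
  expect_identical(dup4$n_multi, 1L)
})

test_that("threshold counts are inclusive and monotone", {
  expect_identical(unname(thresholdCounts(c(0.05, 0.15, 0.25, 0.6))),
                   c(3L, 2L, 1L))
  expect_identical(unname(thresholdCounts(numeric(0))), c(0L, 0L, 0L))
  expect_identical(unname(thresholdCounts(rep(0.10, 7))[1]), 7L)
  set.seed(11)
  tc <- thresholdCounts(runif(100))
  expect_true(all(diff(tc) <= 0))
})
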