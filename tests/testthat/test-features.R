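lib <- syntheticConsensusLibrary()
consY <- as.character(consensusSeqs(lib)[["AluY"]])

test_that("findTerminator returns the first >=minRun T run at or after from", {
  expect_identical(findTerminator("GCATTTTG", 0), 3L)
  expect_identical(findTerminator("TTTATTTA", 0), NA_integer_)
  expect_identical(findTerminator("AAAATTTTTT", 4), 4L)
  expect_identical(findTerminator("TTTTT", 1), 1L)
  expect_error(findTerminator("ACGT", 9), "outside")
})

test_that("findTerminator agrees with a brute-force scan on random strings", {
  set.seed(4242)
  for (i in seq_len(10000)) {
    # T-rich alphabet so terminators actually occur
    s <- randomSeq(sample(5:40, 1), letters = c("A", "C", "G", "T", "T"))
    from <- sample(0:(nchar(s) - 1), 1)
    expect_identical(findTerminator(s, from), oracleFirstTRun(s, from),
                     label = sprintf("seq %s from %d", s, from))
  }
})

test_that("measureATail applies the stop-and-trim rule", {
  # single disruption, stop at flank (3 consecutive non-A)
  r <- measureATail(paste0("AAAAAAAAAAGAAAAAAAAA", "CGCCC"), 0)
  expect_identical(r$a_tail_len, 20L)
  expect_equal(r$a_tail_disruption_pct, 5)
  # terminator interaction: stops at TTTT, trailing non-A trimmed
  r <- measureATail("AAAAAAGAGAAAATTTTCC", 0)
  expect_identical(r$a_tail_len, 13L)
  expect_equal(r$a_tail_disruption_pct, 100 * 2 / 13, tolerance = 1e-12)
  expect_identical(r$tail_end, 13L)
  # three consecutive non-A stop with trailing trim
  r <- measureATail("AAGTCGGGAAA", 0)
  expect_identical(r$a_tail_len, 2L)
  expect_equal(r$a_tail_disruption_pct, 0)
  # empty tail
  r <- measureATail("GGGCCC", 0)
  expect_identical(r$a_tail_len, 0L)
  expect_equal(r$a_tail_disruption_pct, 0)
})

test_that("appending As to a pure tail grows it by exactly that count", {
  base <- "AAAAAAAAAA"
  for (k in c(1L, 5L, 17L)) {
    r <- measureATail(paste0(base, strrep("A", k), "CCGG"), 0)
    expect_identical(r$a_tail_len, 10L + k)
  }
})

test_that("a measured tail never extends past a terminator start", {
  set.seed(515)
  for (i in seq_len(200)) {
    s <- randomSeq(60, letters = c("A", "A", "A", "C", "G", "T"))
    r <- measureATail(s, 0)
    term <- findTerminator(s, 0)
    if (!is.na(term)) expect_lte(r$tail_end, term)
  }
})

test_that("divergence counts substitutions and indel events per consensus column", {
  cons <- fixtureConsensus300()
  library1 <- singleConsensusLibrary(cons)
  # identity
  loc <- locateBody(cons, library1)
  expect_equal(loc$divergence_pct, 0)
  expect_identical(loc$body_start, 0L)
  expect_identical(loc$body_end, 300L)
  # 15 point substitutions over 300 columns -> 5.0%
  subbed <- substituteAt(cons, seq(20, 258, by = 17))
  expect_length(seq(20, 258, by = 17), 15L)
  loc <- locateBody(subbed, library1)
  expect_equal(loc$divergence_pct, 5, tolerance = 1e-12)
  # 8 substitutions + one 4-base deletion = 9 events -> 3.0%
  mut <- substituteAt(cons, seq(30, 240, by = 30))
  mut <- deleteAt(mut, 155, 4)  # disjoint from the substituted positions
  loc <- locateBody(mut, library1)
  expect_equal(loc$divergence_pct, 3, tolerance = 1e-12)
})

test_that("measureUniqueRegion finds the terminator or caps at the window", {
  r <- measureUniqueRegion("GCGTAGCTTTTAA", 0)
  expect_identical(r$unique_len, 7L)
  expect_true(r$terminator_found)
  r <- measureUniqueRegion("TTTTGG", 0)
  expect_identical(r$unique_len, 0L)
  expect_true(r$terminator_found)
  s <- randomSeq(400, letters = c("A", "C", "G"))
  r <- measureUniqueRegion(s, 0, window = 300)
  expect_identical(r$unique_len, 300L)
  expect_false(r$terminator_found)
})

test_that("structural filter passes dimeric loci and rejects decoys with reasons", {
  clean <- generateLocus(locusSpec(divergence = 3, aTailLen = 30,
                                   disruption = 5, uniqueLen = 20, seed = 2),
                         consY)
  loc <- locateBody(clean$sequence, lib)
  expect_identical(structuralFilter(loc, clean$sequence)$structure_ok, TRUE)
  # FLAM-like left-arm-only and internally terminated decoys, many seeds
  for (seed in 1:8) {
    mono <- generateLocus(locusSpec(divergence = 3, aTailLen = 30,
                                    disruption = 5, uniqueLen = 20,
                                    structure = "monomeric", seed = seed),
                          consY)
    f <- structuralFilter(locateBody(mono$sequence, lib), mono$sequence)
    expect_false(f$structure_ok)
    expect_identical(f$reject_reason, "monomeric")
    int <- generateLocus(locusSpec(divergence = 3, aTailLen = 30,
                                   disruption = 5, uniqueLen = 20,
                                   structure = "internally_terminated",
                                   seed = seed), consY)
    f <- structuralFilter(locateBody(int$sequence, lib), int$sequence)
    expect_false(f$structure_ok)
    expect_identical(f$reject_reason, "internal_terminator")
  }
  # a bare TTTT planted mid-body of a clean copy is internal too
  planted <- paste0(substr(consY, 1, 150), "TTTT",
                    substr(consY, 151, nchar(consY)),
                    strrep("A", 30), "CCG", strrep("T", 6))
  f <- structuralFilter(locateBody(planted, lib), planted)
  expect_identical(f$reject_reason, "internal_terminator")
})

test_that("B-box detection respects the motif and the consensus-frame window", {
  ideal <- generateLocus(locusSpec(divergence = 0, aTailLen = 50,
                                   disruption = 0, uniqueLen = 0, seed = 1),
                         consY)
  f <- extractFeatures(AluLocusSet(c(ref = ideal$sequence)), lib)
  expect_true(f$has_b_box)
  # single-position motif break: GTTCGAAAC -> GTACGAAAC at consensus 72
  broken <- ideal$sequence
  substr(broken, 75, 75) <- "A"
  f <- extractFeatures(AluLocusSet(c(broken = broken)), lib)
  expect_false(f$has_b_box)
  # motif present but outside the window
  expect_true(hasBBox(consY, 60, 90))
  expect_false(hasBBox(paste0(randomSeq(150, c("A", "C", "G")), "GTTCGAAAC"),
                       60, 90))
})

test_that("N-heavy loci are rejected and N counts as mismatch otherwise", {
  s <- paste0(substr(consY, 1, 200), strrep("N", 100))
  f <- extractFeatures(AluLocusSet(c(n = s)), lib)
  expect_identical(f$reject_reason, "excess_N")
  # a few N bases count as divergence
  v <- consY
  substr(v, 40, 42) <- "NNN"
  loc <- locateBody(paste0(v, strrep("A", 30), strrep("T", 6)), lib)
  expect_equal(loc$divergence_pct, 100 * 3 / 282, tolerance = 1e-12)
})

test_that("features are recovered from a synthetic cohort", {
  co <- generateCohort(80, seed = 64)
  f <- extractFeatures(co$loci, lib)
  expect_true(all(f$structure_ok))
  expect_identical(f$a_tail_len, co$truth$a_tail_len)
  expect_identical(f$unique_len, co$truth$unique_len)
  expect_identical(f$subfamily, co$truth$subfamily)
  # the full-strength divergence-recovery property (>= 95% within 1 pp at
  # n = 500) runs in the acceptance suite; this smoke check at n = 80
  # allows for the larger sampling noise of the small cohort
  sub15 <- co$truth$divergence_pct <= 15
  expect_gte(mean(abs(f$divergence_pct - co$truth$divergence_pct)[sub15] <= 1),
             0.90)
  expect_true(all(f$terminator_found))
})
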