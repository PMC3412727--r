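# Independent oracles and fixture builders used across the suite.

# brute-force terminator scan: first offset i (0-based) such that
# positions i..i+minRun-1 are all T, checking every position directly
oracleFirstTRun <- function(s, from = 0L, minRun = 4L) {
  v <- strsplit(s, "")[[1]] == "T"
  n <- length(v)
  last <- n - minRun + 1L
  if (last < from + 1L) return(NA_integer_)
  for (i in (from + 1L):last) {
    if (all(v[i:(i + minRun - 1L)])) return(i - 1L)
  }
  NA_integer_
}

randomSeq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# 300-base single-subfamily test consensus with no TTT run and a C/G-rich
# terminal block, used for the divergence-counting fixtures
fixtureConsensus300 <- function() {
  set.seed(300300)
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE,
                      prob = c(0.24, 0.30, 0.30, 0.16)), collapse = "")
    s <- paste0(substr(s, 1, 294), "GCCGGC")
    if (!grepl("TTT", s)) return(s)
  }
}

# substitute 1-based positions to a fixed different non-T base
substituteAt <- function(seq, pos) {
  v <- strsplit(seq, "")[[1]]
  map <- c(A = "C", C = "G", G = "A", T = "C")
  v[pos] <- map[v[pos]]
  paste(v, collapse = "")
}

deleteAt <- function(seq, from, len) {
  paste0(substr(seq, 1, from - 1), substr(seq, from + len, nchar(seq)))
}

# hypergeometric point-probability two-sided p computed from binomial
# coefficients (no dhyper), for the Fisher cross-check
oracleFisherP <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  support <- max(0, n1 - m2):min(m1, n1)
  pmf <- choose(m1, support) * choose(m2, n1 - support) / choose(m1 + m2, n1)
  pObs <- pmf[support == a]
  min(1, sum(pmf[pmf <= pObs * (1 + 1e-7)]))
}

singleConsensusLibrary <- function(seq, name = "AluTest", age = "Y") {
  ConsensusLibrary(setNames(seq, name), setNames(age, name))
}
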