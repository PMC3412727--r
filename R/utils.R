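## evaluate expr under a local RNG stream; global .Random.seed untouched
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## sample n positions from 1..m with pairwise distance >= 2 (uniform over
## all such spaced subsets, via the stars-and-bars bijection)
.sampleSpaced <- function(n, m) {
  if (n == 0L) return(integer(0))
  if (m - (n - 1L) < n)
    stop("cannot place ", n, " positions with spacing >= 2 in ", m, " slots")
  sort(sample.int(m - (n - 1L), n)) + 0:(n - 1L)
}

.pct1 <- function(x) round(x, 1)
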