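# Independent brute-force ROH oracle: enumerate every index pair, test all
# five constraints, then apply the longest-first (ties: leftmost)
# non-overlap selection. Used to pin the segment-mode caller's semantics.

bruteForceRoh <- function(calls, positions, params) {
  m <- length(calls)
  minLen <- params@minLengthKb * 1000
  maxDen <- params@minDensityKbPerSnp * 1000
  maxGap <- params@maxGapKb * 1000
  het <- cumsum(c(0L, !is.na(calls) & calls == 1L))
  mis <- cumsum(c(0L, is.na(calls)))
  gaps <- c(0, diff(positions))
  cand <- list()
  for (i in seq_len(m)) {
    if (i > m) break
    js <- i:m
    nh <- het[js + 1L] - het[i]
    nm <- mis[js + 1L] - mis[i]
    maxg <- cummax(c(0, gaps[setdiff(js, i)]))
    len <- positions[js] - positions[i]
    n <- js - i + 1L
    ok <- nh <= params@maxHet & nm <= params@maxMissing &
      n >= params@minSnps & len >= minLen &
      len <= maxDen * n & maxg <= maxGap
    if (any(ok))
      cand[[length(cand) + 1L]] <-
        data.frame(i = i, j = js[ok], len = len[ok])
  }
  if (!length(cand)) {
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer()))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$len, cand$i, cand$j), , drop = FALSE]
  sel <- logical(0)
  chosen <- cand[0, ]
  for (r in seq_len(nrow(cand))) {
    ci <- cand$i[r]; cj <- cand$j[r]
    if (!nrow(chosen) || all(cj < chosen$i | ci > chosen$j))
      chosen <- rbind(chosen, cand[r, ])
  }
  chosen <- chosen[order(chosen$i), , drop = FALSE]
  data.frame(start_idx = chosen$i, end_idx = chosen$j,
             n_snps = chosen$j - chosen$i + 1L,
             n_het = het[chosen$j + 1L] - het[chosen$i],
             n_missing = mis[chosen$j + 1L] - mis[chosen$i])
}

# reference IBS implementation: explicit double loop, pairwise deletion
naiveIbs <- function(calls) {
  n <- ncol(calls)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(calls[, i]) & !is.na(calls[, j])
    sim <- (2 - abs(calls[ok, i] - calls[ok, j])) / 2
    D[i, j] <- 1 - mean(sim)
  }
  D
}

# random chromosome with mixed het/missing densities
randomChromosome <- function(m, hetRate, missRate, spanBp = m * 20000) {
  pos <- sort(sample.int(spanBp, m))
  g <- sample(c(0L, 2L), m, replace = TRUE)
  g[runif(m) < hetRate] <- 1L
  g[runif(m) < missRate] <- NA_integer_
  list(calls = g, positions = pos)
}
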