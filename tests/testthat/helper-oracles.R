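# Independent oracles and small fixtures shared across tests.

# Direct step-up definition of Benjamini-Hochberg adjusted p-values:
# q_i = min over sorted p_(j) >= p_(i) of p_(j) * m / j, capped at 1.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) ps[j] * m / j, numeric(1))
    q[i] <- min(1, cand)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Exhaustive hypergeometric upper tail P(X >= k): enumerate every size-nA
# subset of a universe of N elements of which nB are "successes".
hyperOracle <- function(k, nA, nB, N) {
  subsets <- utils::combn(N, nA)
  hits <- colSums(subsets <= nB)  # elements 1..nB are the successes
  mean(hits >= k)
}

# Per-element brute-force Venn classification.
vennOracle <- function(a, b, c) {
  all <- unique(c(a, b, c))
  code <- vapply(all, function(g)
    paste0(as.integer(g %in% a), as.integer(g %in% b), as.integer(g %in% c)),
    character(1))
  counts <- table(factor(code, c("100", "010", "001", "110", "101", "011", "111")))
  stats::setNames(as.integer(counts),
                  c("a_only", "b_only", "c_only", "ab", "ac", "bc", "abc"))
}

# Small simulated screen shared by pipeline-level tests.
smallConfig <- function(seed = 11, ...) {
  screenConfig(rows = 8, cols = 12, duration = 24, seed = seed, ...)
}

smallStrains <- sprintf("s%03d", 1:72)
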