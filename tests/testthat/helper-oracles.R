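# Independent brute-force oracles for the two tail tests. Both enumerate
# set placements explicitly (combn) and count, never touching the package's
# log-gamma path, phyper or fisher.test. Exact for the small universes used
# in tests: every count and binomial coefficient involved is far below 2^53.

# P(|X ∩ T1| >= m) where T1 = {1..n1} is fixed and X is a uniformly random
# n2-subset of {1..N}.
oracle_overlap_p <- function(n1, n2, m, N) {
  if (n2 == 0L || n1 == 0L) return(if (m <= 0L) 1 else 0)
  cmb <- combn(N, n2)
  hits <- colSums(cmb <= n1)
  mean(hits >= m)
}

# One-sided Fisher enrichment tail for table (a, b, c, d): with n items of
# which the first r = a + b are "group 1", draw k = a + c items uniformly;
# P(|draw ∩ group1| >= a).
oracle_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r <- a + b
  k <- a + c
  if (n == 0L || k == 0L || r == 0L) return(if (a <= 0L) 1 else 0)
  cmb <- combn(n, k)
  hits <- colSums(cmb <= r)
  mean(hits >= a)
}

# log10 of a binomial coefficient by an arithmetic route independent of
# lchoose/lgamma: sum of log10 of the term-by-term ratio.
oracle_log10_choose <- function(n, k) {
  if (k == 0L) return(0)
  sum(log10((n - k + seq_len(k)) / seq_len(k)))
}
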