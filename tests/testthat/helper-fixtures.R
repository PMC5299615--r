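# small programmatic fixtures shared across test files

# Hardy-Weinberg genotypes for unrelated individuals at independent SNPs
hweGenotypes <- function(n, m, p = NULL) {
  if (is.null(p)) p <- runif(m, 0.1, 0.9)
  geno <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  rownames(geno) <- sprintf("ind%d", seq_len(n))
  colnames(geno) <- sprintf("snp%d", seq_len(m))
  geno
}

# numeric-integration oracle for the mean of a standard normal truncated to
# the upper tail above qnorm(1 - q)
truncMeanOracle <- function(q) {
  lo <- qnorm(1 - q)
  stats::integrate(function(x) x * dnorm(x), lo, Inf,
                   rel.tol = 1e-12)$value / q
}

# O(n^2) pairwise AUC oracle with ties counting one half
aucPairwiseOracle <- function(scores, status) {
  cs <- scores[status == 1]
  ct <- scores[status == 0]
  tot <- 0
  for (x in cs) tot <- tot + sum(x > ct) + 0.5 * sum(x == ct)
  tot / (length(cs) * length(ct))
}
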