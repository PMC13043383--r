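# Vectorized two-sided rank-sum test (midranks, tie-corrected normal
# approximation) applied gene-wise to a cells x genes matrix. Group sizes in
# single-cell comparisons are large enough that the exact distribution is
# never needed here; the exact small-sample path lives in
# wilcoxon_rank_sum().
.rank_sum_p <- function(X, in_group) {
  X <- as.matrix(X)
  n <- nrow(X)
  n1 <- sum(in_group)
  n2 <- n - n1
  stopifnot(n1 > 0, n2 > 0)
  out <- apply(X, 2, function(v) {
    r <- rank(v)
    W <- sum(r[in_group])
    mu <- n1 * (n + 1) / 2
    tlen <- rle(sort(v))$lengths
    tie_term <- sum(tlen^3 - tlen)
    sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sig2 <= 0) return(c(W, 1))
    z <- (W - mu) / sqrt(sig2)
    c(W, 2 * stats::pnorm(-abs(z)))
  })
  list(statistic = out[1, ], p = out[2, ])
}

# log2 fold-change of group means on the normalized (pre-log) scale with a
# pseudocount of 1: norm holds log1p-transformed values, so means are taken
# of expm1(norm)
.log2fc_normalized <- function(norm, in_group) {
  X <- expm1(as.matrix(norm))
  m_in <- colMeans(X[in_group, , drop = FALSE])
  m_out <- colMeans(X[!in_group, , drop = FALSE])
  log2((m_in + 1) / (m_out + 1))
}
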