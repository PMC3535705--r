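# Independent brute-force oracles used by several test files.

# two-sided rank-sum p by listing every group assignment of the pooled values
perm_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  m <- length(a)
  w_obs <- sum(r[seq_len(m)])
  ws <- apply(utils::combn(length(pooled), m), 2L, function(i) sum(r[i]))
  min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
}

# direct step-up definition of Benjamini-Hochberg
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(o == i)  # rank of p[i]
    q[i] <- min(1, min(sort(p)[j:m] * m / (j:m)))
  }
  q
}
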