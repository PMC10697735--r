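# Small simulated fixtures shared across test files; all built in code.

# Correlated binary phenotype matrix with exactly round(n*r) cases per
# column (single shared factor, any K).
random_binary_phenos <- function(n, K, r = 0.05, seed = 1) {
  set.seed(seed)
  f <- rnorm(n)
  liab <- 0.6 * f + matrix(rnorm(n * K), n, K)
  dichotomize(liab, r = r)
}

# Block-structured similarity matrix: two blocks with high within- and low
# between-block similarity.
two_block_W <- function(sizes = c(4, 4), within = 0.9, between = 0) {
  K <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  W <- matrix(between, K, K)
  W[outer(lab, lab, "==")] <- within
  diag(W) <- 1
  W
}

# Brute-force co-occurrence count: the literal triple loop over
# individuals and phenotype pairs.
adjacency_bruteforce <- function(Y) {
  n <- nrow(Y); K <- ncol(Y)
  A <- matrix(0L, K, K)
  for (i in seq_len(n))
    for (j in seq_len(K))
      for (k in seq_len(K))
        A[j, k] <- A[j, k] + Y[i, j] * Y[i, k]
  A
}

# Brute-force modularity: the literal double loop over ordered pairs.
modularity_bruteforce <- function(W, labels) {
  K <- ncol(W)
  d <- rowSums(W)
  twoD <- sum(d)
  q <- 0
  for (j in seq_len(K))
    for (k in seq_len(K))
      if (labels[j] == labels[k])
        q <- q + W[j, k] - d[j] * d[k] / twoD
  q / twoD
}
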