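# Small in-code fixtures shared across test files.

# Evidence matrix with given gene names and a genes x 7 score matrix
# (scores recycled row-wise when a vector is given).
toy_evidence <- function(genes, scores) {
  m <- if (is.matrix(scores)) scores
       else matrix(scores, nrow = length(genes), ncol = 7, byrow = TRUE)
  rownames(m) <- genes
  evidence_matrix(m)
}

# Deterministic pseudo-random evidence matrix on n genes.
random_evidence <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(round(runif(n * 7, 0, 5), 2), nrow = n)
  rownames(m) <- sprintf("G%03d", seq_len(n))
  evidence_matrix(m)
}

unit_preweight <- function() rep(1, 7)

# Full-enumeration rank-sum oracle: iterates every subset of size m via
# bitmasks (independent of the package's combination-based exact path).
oracle_ranksum_p <- function(x, y, alternative = "less") {
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(m)])
  stats <- c()
  for (s in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(s)[1:N])
    if (sum(bits) == m) stats <- c(stats, sum(r[bits == 1]))
  }
  switch(alternative,
         less = mean(stats <= obs + 1e-9),
         greater = mean(stats >= obs - 1e-9),
         two.sided = min(1, 2 * min(mean(stats <= obs + 1e-9),
                                    mean(stats >= obs - 1e-9))))
}
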