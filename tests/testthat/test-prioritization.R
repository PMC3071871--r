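test_that("combined_score is the pre-weighted weighted sum", {
  pre <- default_preweight()
  W <- c(2, 1, 1, 8, 1, 1, 7)
  expect_equal(combined_score(rep(0, 7), W, pre), 0)
  expect_equal(combined_score(rep(1, 7), W, pre), 15)
  S <- c(1, 2, 0, 3, 0.5, 0, 1)
  expect_equal(combined_score(S, W, pre), sum(pre * S * W))
  expect_error(combined_score(rep(1, 6), W, pre), "length 7")
  expect_error(combined_score(rep(1, 7), c(0, rep(1, 6)), pre), "integers >= 1")
})

test_that("weight-vector enumeration is lexicographic and complete", {
  expect_equal(weight_vector_block(1, 10, n_sources = 1, d = 2),
               matrix(1:2, ncol = 1))
  g <- weight_vector_block(1, 100, n_sources = 2, d = 3)
  expect_equal(nrow(g), 9)
  expect_equal(g[1, ], c(1L, 1L))
  expect_equal(g[2, ], c(1L, 2L))    # last source varies fastest
  expect_equal(g[9, ], c(3L, 3L))
  expect_equal(nrow(unique(g)), 9)

  # block streaming partitions the pool without gaps or overlap
  for (cfg in list(c(3, 4), c(4, 3), c(2, 8))) {
    N <- cfg[1]; d <- cfg[2]
    whole <- weight_vector_block(1, d^N, N, d)
    blocks <- enumerate_weight_vectors(identity, n_sources = N, d = d,
                                       block_size = 7L)
    expect_equal(do.call(rbind, blocks), whole)
    expect_equal(nrow(whole), n_weight_vectors(N, d))
    expect_equal(nrow(unique(whole)), d^N)
  }
})

test_that("rank_genes orders by descending score with identifier tie-break", {
  E <- toy_evidence(c("GENEB", "GENEA", "GENEC"),
                    rbind(c(5, rep(0, 6)), c(5, rep(0, 6)), c(3, rep(0, 6))))
  r <- rank_genes(E, rep(1, 7), unit_preweight())
  expect_equal(r$gene, c("GENEA", "GENEB", "GENEC"))
  expect_equal(r$combined_score, c(5, 5, 3))
  expect_equal(r$rank, 1:3)
})

test_that("rankings are invariant to scaling all weights", {
  E <- random_evidence(40, seed = 7)
  r1 <- rank_genes(E, rep(1, 7), unit_preweight())
  r2 <- rank_genes(E, rep(3, 7), unit_preweight())
  expect_equal(r1$gene, r2$gene)
  expect_equal(r2$combined_score, 3 * r1$combined_score)
})

test_that("raising a source weight never demotes a gene scored only there", {
  set.seed(31)
  for (rep in 1:5) {
    E <- random_evidence(30, seed = rep)
    m <- unclass(E)
    m["G001", ] <- c(0, 0, 2, 0, 0, 0, 0)  # expression_human only
    E <- evidence_matrix(m)
    prev <- Inf
    for (w3 in 1:6) {
      W <- c(1, 1, w3, 1, 1, 1, 1)
      pos <- match("G001", rank_genes(E, W, unit_preweight())$gene)
      expect_lte(pos, prev)
      prev <- pos
    }
  }
})

test_that("core gene positions match hand counts", {
  genes <- sprintf("G%02d", 1:10)
  core <- core_gene_set(genes[c(2, 5, 9)])
  expect_equal(core_gene_positions(genes, core, phi = 0.9),
               list(position_j = 9L, position_l = 9L, m = 3))
  expect_equal(core_gene_positions(genes, core, phi = 0.6),
               list(position_j = 5L, position_l = 9L, m = 2))
  # all core genes on top: j = ceiling(phi K), l = K
  coreK <- core_gene_set(genes[1:4])
  p <- core_gene_positions(genes, coreK, phi = 0.6)
  expect_equal(p$position_j, 3L)
  expect_equal(p$position_l, 4L)
  expect_error(core_gene_positions(genes, core_gene_set(c("X1", "X2"))),
               "missing")
})

test_that("j <= l always, and phi = 1 makes them equal", {
  for (seed in 1:10) {
    set.seed(seed)
    genes <- sample(sprintf("G%02d", 1:30))
    core <- core_gene_set(sample(genes, 5))
    for (phi in c(0.3, 0.7, 1)) {
      p <- core_gene_positions(genes, core, phi)
      expect_lte(p$position_j, p$position_l)
      if (phi == 1) expect_equal(p$position_j, p$position_l)
    }
  }
})

test_that("select_matrices applies the eta threshold arithmetic", {
  # 100 genes; core genes G001, G002 sit on top under high w1
  scores <- matrix(0, 100, 7)
  scores[, 1] <- c(10, 9, runif(98, 0, 5))
  rownames(scores) <- sprintf("G%03d", 1:100)
  E <- evidence_matrix(scores)
  core <- core_gene_set(c("G001", "G002"))
  grid <- matrix(c(5, 1, 1, 1, 1, 1, 1), nrow = 1)
  res5 <- select_matrices(E, core, unit_preweight(), phi = 1, eta = 0.05,
                          grid = grid)
  expect_true(res5$passed)            # j = 2 <= ceiling(0.05*100) = 5
  res1 <- select_matrices(E, core, unit_preweight(), phi = 1, eta = 0.01,
                          grid = grid)
  expect_equal(res1$position_j, 2L)
  expect_false(res1$passed)           # threshold ceiling(0.01*100) = 1 < j
})

test_that("hard position criteria act as post-filters on top of eta", {
  E <- random_evidence(50, seed = 3)
  core <- core_gene_set(rownames(E)[1:4])
  grid <- weight_vector_block(1, 16, n_sources = 7, d = 2)
  base <- select_matrices(E, core, unit_preweight(), phi = 1, eta = 0.9,
                          grid = grid)
  hard <- select_matrices(E, core, unit_preweight(), phi = 1, eta = 0.9,
                          grid = grid, max_l = min(base$position_l))
  expect_true(all(hard$passed == (base$passed &
                                    base$position_l == min(base$position_l))))
})
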