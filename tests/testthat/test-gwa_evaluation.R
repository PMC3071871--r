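toy_snps <- function(pos, p, chrom = "chr1") {
  data.frame(snp = sprintf("rs%03d", seq_along(pos)), chrom = chrom,
             pos = pos, p = p, stringsAsFactors = FALSE)
}

test_that("SNPs map to genes inside the body plus the flanking window", {
  coords <- gene_coordinates("GENEA", "chr1", 10000, 11000)
  expect_equal(map_snps_to_genes(toy_snps(10500, 0.5), coords)$gene, "GENEA")
  # inclusive window boundaries
  expect_equal(nrow(map_snps_to_genes(toy_snps(31000, 0.5), coords)), 1)
  expect_equal(nrow(map_snps_to_genes(toy_snps(31001, 0.5), coords)), 0)
  expect_equal(nrow(map_snps_to_genes(toy_snps(31500, 0.5), coords)), 0)
  # a gene's representative p is the minimum over its SNPs
  g <- map_snps_to_genes(toy_snps(c(10100, 10200, 10300), c(0.2, 0.01, 0.8)),
                         coords)
  expect_equal(g$p, 0.01)
  expect_equal(g$n_snps, 3L)
})

test_that("mapping ignores SNP input order and unknown chromosomes warn", {
  coords <- gene_coordinates(c("A", "B"), "chr1", c(1000, 50000),
                             c(2000, 60000))
  snps <- toy_snps(c(1500, 55000, 1200), c(0.5, 0.3, 0.1))
  shuffled <- snps[c(3, 1, 2), ]
  expect_equal(map_snps_to_genes(snps, coords),
               map_snps_to_genes(shuffled, coords))
  snps2 <- rbind(snps, toy_snps(100, 0.2, chrom = "chrX"))
  expect_warning(g <- map_snps_to_genes(snps2, coords), "skipped")
  expect_equal(g, map_snps_to_genes(snps, coords))
})

test_that("rank-sum exact p-values match hand enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4), "less"), 1 / 6)
  expect_equal(wilcoxon_rank_sum(c(3, 4), c(1, 2), "greater"), 1 / 6)
  x <- c(1, 2, 3)
  expect_gte(wilcoxon_rank_sum(x, x, "less"), 0.5)
})

test_that("exact rank-sum agrees with the full-enumeration oracle, ties included", {
  set.seed(99)
  for (m in 1:4) for (n in 2:5) {
    x <- sample(1:4, m, replace = TRUE)       # integer values force ties
    y <- sample(1:4, n, replace = TRUE)
    for (alt in c("less", "greater", "two.sided")) {
      expect_equal(wilcoxon_rank_sum(x, y, alt), oracle_ranksum_p(x, y, alt),
                   tolerance = 1e-12,
                   info = sprintf("m=%d n=%d alt=%s", m, n, alt))
    }
  }
})

test_that("tie-free exact p-values match the reference distribution", {
  set.seed(7)
  for (i in 1:10) {
    x <- runif(4); y <- runif(5)
    expect_equal(wilcoxon_rank_sum(x, y, "less"),
                 wilcox.test(x, y, alternative = "less", exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("the normal approximation is sound for large shifted samples", {
  set.seed(11)
  x <- runif(50) / 1000
  y <- runif(50)
  expect_lt(wilcoxon_rank_sum(x, y, "less"), 1e-6)
  expect_gt(wilcoxon_rank_sum(y, x, "less"), 0.99)
  # close to the reference implementation on null data
  x <- runif(40); y <- runif(40)
  expect_equal(wilcoxon_rank_sum(x, y, "less"),
               wilcox.test(x, y, alternative = "less", exact = FALSE,
                           correct = TRUE)$p.value,
               tolerance = 1e-10)
})

null_gwa <- function(n, seed) {
  set.seed(seed)
  structure(data.frame(gene = sprintf("G%04d", 1:n), p = runif(n),
                       n_snps = 1L, stringsAsFactors = FALSE),
            class = c("gwa_gene_table", "data.frame"))
}

test_that("evaluation counts stay within bounds and sd is 0 for one repeat", {
  gwa <- null_gwa(30, seed = 5)
  ev <- evaluate_prioritized_set(gwa$gene, gwa, j = 30, n_random = 1,
                                 repeats = 1, seed = 2)
  expect_true(ev$mean %in% c(0, 1))
  expect_equal(ev$sd, 0)
  ev <- evaluate_prioritized_set(gwa$gene, gwa, j = 10, n_random = 25,
                                 repeats = 3, seed = 2)
  expect_true(all(ev$counts >= 0 & ev$counts <= 25))
  expect_gte(ev$sd, 0)
})

test_that("evaluation is reproducible under a seed and rejects bad input", {
  gwa <- null_gwa(50, seed = 6)
  a <- evaluate_prioritized_set(gwa$gene, gwa, j = 15, n_random = 20,
                                repeats = 2, seed = 9)
  b <- evaluate_prioritized_set(gwa$gene, gwa, j = 15, n_random = 20,
                                repeats = 2, seed = 9)
  expect_identical(a$counts, b$counts)
  expect_error(evaluate_prioritized_set(gwa$gene, gwa, j = 51, n_random = 5),
               "universe|ranking")
  expect_error(evaluate_prioritized_set(c("NOPE1", "NOPE2"), gwa, j = 2,
                                        n_random = 5),
               "GWA p-value")
})

test_that("a strongly enriched prioritized set beats nearly all random sets", {
  set.seed(123)
  n <- 600
  gwa <- structure(
    data.frame(gene = sprintf("G%04d", 1:n),
               p = c(runif(150)^5, runif(n - 150)),  # Beta(0.2,1) head
               n_snps = 1L, stringsAsFactors = FALSE),
    class = c("gwa_gene_table", "data.frame"))
  ev <- evaluate_prioritized_set(gwa$gene, gwa, j = 150, n_random = 200,
                                 repeats = 2, seed = 4)
  expect_gt(ev$mean / ev$n_random, 0.95)
})
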