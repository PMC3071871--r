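test_that("association scoring follows the two-criteria table", {
  expect_equal(score_association(0, 0), 0)
  expect_equal(score_association(20, 16), 4)     # many studies, mostly positive
  expect_equal(score_association(1, 1), 1)       # extreme proportion damped
  expect_equal(score_association(11, 2), 1)      # many studies, few positive
  expect_equal(score_association(3, 3), 2)
  expect_error(score_association(2, 3), "n_positive")
})

test_that("association scoring is monotone in both criteria", {
  ns <- c(0, 1, 2, 3, 5, 6, 10, 11, 30)
  for (frac in c(0, 0.3, 0.6, 1)) {
    s <- score_association(ns, floor(frac * ns))
    expect_true(all(diff(s) >= 0), info = paste("proportion", frac))
  }
  for (n in c(4, 8, 20))
    expect_true(all(diff(score_association(rep(n, 5), round(n * c(0, .25, .5, .75, 1)))) >= 0))
})

test_that("non-monotone association tables are rejected at load", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("study_bands: [0, 1, 3]",
               "proportion_bands: [0.0, 0.5]",
               "scores:", "  - [0, 0]", "  - [2, 1]", "  - [2, 3]"), f)
  expect_error(default_association_table(f), "monotone")
})

test_that("linkage scoring takes the max statistic and zeroes weak signals", {
  expect_equal(score_linkage(lod = 0.8), 0)
  expect_equal(score_linkage(lod = 2.0, neglog10p = 4.6), 4.6)
  expect_equal(score_linkage(lod = 1.0), 1.0)
  expect_equal(score_linkage(neglog10p = 2.5), 2.5)
  expect_error(score_linkage(), "at least one")
  expect_error(score_linkage(lod = -1), ">= 0")
})

test_that("expression scoring is -log10 p below the extraction filter, else 0", {
  expect_equal(score_expression(0.001), 3)
  expect_equal(score_expression(0.5), 0)
  expect_equal(score_expression(0.05), 0)        # boundary fails p < 0.05
  expect_equal(score_expression(2.5e-6), -log10(2.5e-6), tolerance = 1e-12)
  expect_gt(score_expression(2.5e-6), 5.59)      # near the animal-range max
  expect_error(score_expression(0), "\\(0, 1\\]")
  expect_error(score_expression(1.2), "\\(0, 1\\]")
})

test_that("expression scoring is continuous and decreasing below the filter", {
  p <- sort(runif(50, 1e-8, 0.049999))
  s <- score_expression(p)
  expect_true(all(diff(s) <= 0))
  expect_equal(s, -log10(p))
})

test_that("literature scoring counts distinct vocabulary keywords", {
  voc <- literature_vocabulary("human")
  expect_equal(score_literature(character(0)), 0)
  expect_equal(score_literature(voc), 6)
  expect_equal(score_literature(voc[1:4]), 4)
  expect_equal(score_literature(c(voc[1], voc[1])), 1)
  expect_error(score_literature("astrocyte"), "vocabulary")
  expect_equal(score_literature(literature_vocabulary("animal")[1:3],
                                vocabulary = literature_vocabulary("animal")), 3)
})

test_that("pathway scoring takes the strongest mechanism", {
  expect_equal(score_pathway(c("monoamine", "other")), 3)
  expect_equal(score_pathway("hpa_axis"), 2)
  expect_equal(score_pathway(character(0)), 0)
  expect_error(score_pathway("glia"), "unknown")
})

test_that("build_evidence_matrix assembles the seven sources with zeros for absent evidence", {
  E <- build_evidence_matrix(pathway = data.frame(gene = "g1", mechanisms = "other"))
  expect_equal(unname(unclass(E)["G1", ]), c(0, 0, 0, 0, 1, 0, 0))

  # one gene at each source's default maximum
  E <- build_evidence_matrix(
    association = data.frame(gene = "g", n_studies = 30, n_positive = 30),
    linkage = data.frame(gene = "g", lod = 4.6, neglog10p = NA),
    expression_human = data.frame(gene = "g", p_value = 10^-4.6),
    literature_human = data.frame(gene = "g",
      keywords = paste(literature_vocabulary("human"), collapse = ",")),
    pathway = data.frame(gene = "g", mechanisms = "monoamine,other"),
    expression_animal = data.frame(gene = "g", p_value = 10^-5.6),
    literature_animal = data.frame(gene = "g",
      keywords = paste(literature_vocabulary("animal")[1:4], collapse = ",")))
  expect_equal(unname(unclass(E)["G", ]), c(4, 4.6, 4.6, 6, 3, 5.6, 4),
               tolerance = 1e-9)

  expect_equal(nrow(build_evidence_matrix()), 0)
})

test_that("raw evidence files round-trip through read_raw_evidence", {
  dir <- withr::local_tempdir()
  write.table(data.frame(gene = c("a", "b"), n_studies = c(5, 0),
                         n_positive = c(4, 0)),
              file.path(dir, "association.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = "c", p_value = 0.01),
              file.path(dir, "expression_human.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  E <- read_raw_evidence(dir)
  expect_setequal(rownames(E), c("A", "B", "C"))
  expect_equal(unclass(E)["A", "association"], score_association(5, 4))
  expect_equal(unclass(E)["C", "expression_human"], 2)
  expect_equal(sum(unclass(E)["B", ]), 0)
})
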