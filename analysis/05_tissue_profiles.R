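#!/usr/bin/env Rscript
# Step 5: compare tissue expression profiles of the prioritized genes
# against background (non-planted) genes.

library(depgenes)

study_dir <- "results/synthetic_study"
M <- read_tissue_matrix(file.path(study_dir, "tissue_matrix.tsv"))
truth <- readLines(file.path(study_dir, "truth.txt"))
dep <- read.delim("results/depgenes.tsv")

bg <- setdiff(colnames(M), truth)
res <- compare_tissue_profiles(M, dep$gene, bg, alternative = "greater")
res$proportions <- res$proportions[order(-res$proportions$difference), ]
write.table(res$proportions, "results/tissue_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("top per-tissue differences (prioritized - background):\n")
print(head(res$proportions, 5), row.names = FALSE)
cat(sprintf("signed-rank p across %d tissues: %.4f\n", nrow(res$proportions),
            res$p_value))
cat("(the three brain-like tissues carry the planted enrichment;",
    "the nine neutral tissues dilute the across-tissue test)\n")
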