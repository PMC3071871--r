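# depgenes

Evidence-based prioritization of disease candidate genes by multi-source
integration, built around the depression (MDD) candidate-gene problem:
hundreds of genes are implicated by association studies, linkage scans,
expression arrays, literature mining and pathway membership, yet the
sources are too heterogeneous to pool by meta-analysis.  `depgenes` is for
researchers who want a ranked, cutoff-selected candidate list (here called
DEPgenes) with the weighting of sources chosen by the data rather than by
fiat.

## The method

Each gene *g* gets a per-source score `S_i` on that source's own scale
(association 0–4 from a study-count × positive-proportion table; linkage
max(LOD, −log₁₀p) when ≥ 1; expression −log₁₀p when p < 0.05; literature
keyword-hit counts 0–6; pathway 1–3 by mechanism).  Scores combine as

```
C(g) = Σᵢ preWeightᵢ · Sᵢ · Wᵢ ,   i = 1..7
```

where `preWeight` (0.5–1.5) adjusts for unequal score ranges and
`W ∈ {1..d}⁷` is an integer source-weight vector.  The whole pool of `d⁷`
weight vectors (8⁷ = 2,097,152 at full scale) is enumerated exhaustively;
a matrix is retained when it ranks a proportion φ of a curated **core gene
set** within the top η of the candidate ranking (summarised by *position
j*, the rank of the ⌈φK⌉-th core gene, and *position l*, the rank of the
last).  Survivors are then evaluated against genome-wide association
results: SNP p-values are mapped to genes (min p within gene ± 20 kb) and
the top-j prioritized genes are compared with 1000 random same-size gene
sets by one-sided Wilcoxon rank-sum; the matrix beating the most random
sets wins.  Genes scoring at or above a separation-maximizing cutoff under
the optimal matrix form the final list.

## Worked example

The package bundles no restricted data; `generate_study()` creates a fully
synthetic study with planted truth (500 genes, 25 true genes with signal in
the association and human-literature sources, GWA p-values enriched at
true genes).  The numbered scripts under `analysis/` run the whole
workflow; condensed:

```r
library(depgenes)

st  <- generate_study(synthetic_config(seed = 20260927))
gwa <- map_snps_to_genes(st$snps, st$coords, window = 20000)
run <- run_prioritization(st$evidence, st$core, gwa,
                          phi = 0.9, eta = 0.1, grid = 4L,
                          n_random = 1000, repeats = 10, seed = 20260927)
print(run)
#> Prioritization run
#>   matrices passing core-gene criteria: 6613 of 16384
#>   optimal weight matrix: [2,1,1,3,1,1,1] (mean 1000.0 of 1000 random sets)
#>   cutoff 13.5 -> 25 prioritized genes

mean(run$depgenes$gene %in% st$truth)   # precision vs planted truth
#> [1] 1
```

Reading the output: 6,613 of the 16,384 candidate weight matrices place 9
of the 10 core genes inside the top 10% of the ranking; the selected
matrix up-weights exactly the two evidence sources that carry the planted
signal (association and human literature, weights 2 and 3) and leaves the
five noise sources at weight 1; its top-j prioritized set beat all 1000
random gene sets on GWA p-values in every repeat; and the 25 genes at or
above the suggested cutoff are exactly the 25 planted true genes.

The reference study's published outputs are packaged for comparison:
`load_fixture_depgenes()` returns the printed 169-gene list (scores
47.74 down to 15.18) and `load_fixture_core_genes()` the 14-gene core set
used to select its optimal matrix [2,1,1,8,1,1,7].

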