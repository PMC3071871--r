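#' Configuration for the synthetic study generator
#'
#' The generator emulates the statistical structure the prioritization
#' pipeline assumes: a gene universe with sparse background evidence across
#' the seven sources, a planted set of true disease genes enriched in a
#' chosen subset of sources, a core gene set drawn from the truth, SNP-level
#' GWA results enriched for small p-values among true genes, and a binary
#' tissue presence matrix with a brain-like block where true genes are
#' over-represented.
#'
#' @param n_genes Gene universe size.
#' @param n_true Number of planted true disease genes.
#' @param informative_sources Sources carrying the planted signal.
#' @param effect Per-source mean score uplift for true genes (added to the
#'   background draw and clipped to the source's score range).
#' @param gwa_beta_a Beta(a, 1) shape in (0, 1] for true-gene SNP p-values
#'   (1 = no enrichment, smaller = stronger enrichment).
#' @param n_snps_per_gene SNPs simulated inside each gene.
#' @param n_core Core gene set size (sampled from the truth set).
#' @param background_rate Probability a background gene has non-zero
#'   evidence in a given source.
#' @param seed Root integer seed; each generator draws from an independent
#'   derived stream.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 500L, n_true = 25L,
                             informative_sources = c("association",
                                                     "literature_human"),
                             effect = 3, gwa_beta_a = 0.2,
                             n_snps_per_gene = 3L, n_core = 10L,
                             background_rate = 0.1, seed = 1L) {
  stopifnot(n_true <= n_genes, n_core <= n_true, n_core >= 2L,
            gwa_beta_a > 0, gwa_beta_a <= 1, effect >= 0,
            n_snps_per_gene >= 1L, background_rate >= 0, background_rate <= 1)
  bad <- setdiff(informative_sources, evidence_sources())
  if (length(bad))
    stop("unknown sources: ", paste(bad, collapse = ", "))
  structure(list(n_genes = as.integer(n_genes), n_true = as.integer(n_true),
                 informative_sources = informative_sources,
                 effect = effect, gwa_beta_a = gwa_beta_a,
                 n_snps_per_gene = as.integer(n_snps_per_gene),
                 n_core = as.integer(n_core),
                 background_rate = background_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Upper ends of the seven per-source score ranges (association 0-4,
# linkage 0-4.6, human expression 0-4.6, human literature 0-6, pathway 0-3,
# animal expression 0-5.6, animal literature 0-4).
source_score_max <- function() {
  stats::setNames(c(4, 4.6, 4.6, 6, 3, 5.6, 4), evidence_sources())
}

#' Generate a synthetic evidence matrix with planted true genes
#'
#' Background genes carry sparse evidence: each source is non-zero with
#' probability `background_rate`, with magnitude uniform over that source's
#' score range.  True genes additionally receive the `effect` uplift in
#' each informative source, clipped to the source range.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `evidence` (an [evidence_matrix()]) and `truth`
#'   (character vector of true gene identifiers, plus the config as
#'   attribute `config`).
#' @export
generate_evidence <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(derive_seed(cfg$seed, 1L))
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  rng <- source_score_max()
  sc <- matrix(0, nrow = cfg$n_genes, ncol = 7L,
               dimnames = list(genes, evidence_sources()))
  for (s in evidence_sources()) {
    on <- stats::runif(cfg$n_genes) < cfg$background_rate
    sc[on, s] <- stats::runif(sum(on), 0, rng[[s]])
  }
  true_genes <- sort(sample(genes, cfg$n_true))
  for (s in cfg$informative_sources)
    sc[true_genes, s] <- pmin(sc[true_genes, s] + cfg$effect, rng[[s]])
  truth <- structure(true_genes, config = cfg)
  list(evidence = evidence_matrix(sc), truth = truth)
}

#' Sample a core gene set from the planted truth
#'
#' @param truth True gene identifiers from [generate_evidence()].
#' @param cfg The same [synthetic_config()].
#' @return A [core_gene_set()] of size `cfg$n_core`.
#' @export
generate_core_genes <- function(truth, cfg) {
  set.seed(derive_seed(cfg$seed, 2L))
  core_gene_set(sample(as.character(truth), cfg$n_core))
}

#' Generate synthetic SNP-level GWA results and gene coordinates
#'
#' Genes are laid out on one synthetic chromosome as non-overlapping 10 kb
#' intervals spaced 50 kb apart (so even 20 kb flanking windows never
#' bridge neighbours), with `n_snps_per_gene` SNPs uniformly placed inside
#' each gene body.  SNP p-values are Uniform(0, 1) for background genes and
#' Beta(`gwa_beta_a`, 1) for true genes.
#'
#' @param truth True gene identifiers.
#' @param cfg A [synthetic_config()].
#' @return List with `snps` (data frame `snp`, `chrom`, `pos`, `p`) and
#'   `coords` (a [gene_coordinates()] table covering every gene).
#' @export
generate_gwa <- function(truth, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(derive_seed(cfg$seed, 3L))
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  start <- (seq_len(cfg$n_genes) - 1L) * 50000 + 1
  coords <- gene_coordinates(genes, "chrS", start, start + 9999)
  k <- cfg$n_snps_per_gene
  pos <- unlist(lapply(seq_len(cfg$n_genes), function(i)
    sort(sample(seq(coords$start[i], coords$end[i]), k))))
  is_true <- rep(genes %in% truth, each = k)
  u <- stats::runif(cfg$n_genes * k)
  p <- ifelse(is_true, u^(1 / cfg$gwa_beta_a), u)  # Beta(a,1) via inversion
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  snps <- data.frame(snp = sprintf("rs%06d", seq_along(pos)),
                     chrom = "chrS", pos = pos, p = p,
                     gene = rep(genes, each = k), stringsAsFactors = FALSE)
  list(snps = snps[c("snp", "chrom", "pos", "p")], coords = coords)
}

#' Generate a synthetic tissue presence matrix
#'
#' Twelve tissues: a three-tissue brain-like block (`brain`, `nervous`,
#' `cerebrum`) where true genes are present with probability 0.8 versus
#' 0.4 for background genes, and nine neutral tissues where every gene is
#' present with probability 0.5.
#'
#' @param truth True gene identifiers.
#' @param cfg A [synthetic_config()].
#' @return A [tissue_expression_matrix()] (12 tissues x `n_genes` genes);
#'   the enriched tissues are recorded in attribute `enriched_tissues`.
#' @export
generate_tissue_matrix <- function(truth, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(derive_seed(cfg$seed, 4L))
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  enriched <- c("brain", "nervous", "cerebrum")
  tissues <- c(enriched, sprintf("tissue%02d", seq_len(9L)))
  M <- matrix(0L, nrow = length(tissues), ncol = cfg$n_genes,
              dimnames = list(tissues, genes))
  pr_true <- 0.8; pr_bg <- 0.4; pr_neutral <- 0.5
  is_true <- genes %in% truth
  for (t in tissues) {
    pr <- if (t %in% enriched) ifelse(is_true, pr_true, pr_bg) else pr_neutral
    M[t, ] <- as.integer(stats::runif(cfg$n_genes) < pr)
  }
  out <- tissue_expression_matrix(M)
  attr(out, "enriched_tissues") <- enriched
  out
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper producing every input the pipeline consumes.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `evidence`, `truth`, `core`, `snps`, `coords`,
#'   `tissue`, `config`.
#' @export
generate_study <- function(cfg = synthetic_config()) {
  ev <- generate_evidence(cfg)
  core <- generate_core_genes(ev$truth, cfg)
  gwa <- generate_gwa(ev$truth, cfg)
  tissue <- generate_tissue_matrix(ev$truth, cfg)
  list(evidence = ev$evidence, truth = as.character(ev$truth), core = core,
       snps = gwa$snps, coords = gwa$coords, tissue = tissue, config = cfg)
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Writes `evidence.tsv` (scored evidence table), `core_genes.txt`,
#' `snps.tsv`, `gene_coords.tsv` (1-based inclusive), `tissue_matrix.tsv`
#' and `truth.txt` under `dir`.
#'
#' @param study Output of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_inputs <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_evidence_table(study$evidence, file.path(dir, "evidence.tsv"))
  writeLines(as.character(study$core), file.path(dir, "core_genes.txt"))
  utils::write.table(study$snps, file.path(dir, "snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$coords[c("chrom", "start", "end", "gene")],
                     file.path(dir, "gene_coords.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  tm <- data.frame(tissue = rownames(study$tissue), unclass(study$tissue),
                   check.names = FALSE)
  utils::write.table(tm, file.path(dir, "tissue_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(study$truth, file.path(dir, "truth.txt"))
  invisible(dir)
}
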