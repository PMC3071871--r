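#' Map SNP association results to genes by minimum p-value
#'
#' A SNP is assigned to every gene whose body, extended by `window` base
#' pairs up- and downstream (boundaries inclusive), contains its position
#' on the same chromosome.  Each gene's representative association signal
#' is the smallest p-value among its assigned SNPs; genes with no SNP are
#' absent from the result.
#'
#' @param snps Data frame with columns `snp`, `chrom`, `pos` (1-based) and
#'   `p` in (0, 1].
#' @param coords Gene coordinate table from [gene_coordinates()].
#' @param window Flanking window in base pairs (default 20,000).
#' @return Data frame `gene`, `p`, `n_snps`, sorted by gene; class
#'   `gwa_gene_table`.
#' @export
map_snps_to_genes <- function(snps, coords, window = 20000) {
  stopifnot(window >= 0)
  if (any(snps$p <= 0 | snps$p > 1)) stop("SNP p-values must lie in (0, 1]")
  if (any(snps$pos < 1)) stop("SNP positions must be >= 1")
  known <- snps$chrom %in% coords$chrom
  if (!all(known)) {
    warning(sum(!known), " SNP(s) on chromosomes absent from the ",
            "coordinate table were skipped")
    snps <- snps[known, , drop = FALSE]
  }
  gene_gr <- GenomicRanges::GRanges(
    seqnames = coords$chrom,
    ranges = IRanges::IRanges(start = pmax(1, coords$start - window),
                              end = coords$end + window))
  snp_gr <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  if (!length(hits)) {
    out <- data.frame(gene = character(), p = numeric(), n_snps = integer(),
                      stringsAsFactors = FALSE)
  } else {
    g <- coords$gene[S4Vectors::subjectHits(hits)]
    p <- snps$p[S4Vectors::queryHits(hits)]
    out <- data.frame(
      gene = sort(unique(g)),
      p = as.numeric(tapply(p, g, min)[sort(unique(g))]),
      n_snps = as.integer(table(g)[sort(unique(g))]),
      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("gwa_gene_table", "data.frame")
  out
}

#' Two-sample Wilcoxon rank-sum test on p-value samples
#'
#' Mid-ranks are used for ties.  For pooled sample sizes up to 20 the
#' p-value is exact, from full enumeration of the C(n, m) allocations of
#' pooled ranks to the first sample (so ties are handled exactly too);
#' larger samples use the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"less"` (x stochastically smaller), `"greater"`, or
#'   `"two.sided"`.
#' @param exact_max Largest pooled size for the exact path (default 20).
#' @return The p-value.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("less", "greater", "two.sided"),
                              exact_max = 20L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))              # mid-ranks
  w <- sum(r[seq_len(m)])         # rank sum of x
  if (m + n <= exact_max) {
    comb <- utils::combn(m + n, m)
    stats_all <- colSums(matrix(r[comb], nrow = m))
    p_le <- mean(stats_all <= w + 1e-9)
    p_ge <- mean(stats_all >= w - 1e-9)
  } else {
    mu <- m * (m + n + 1) / 2
    tie_tab <- table(r)
    sigma2 <- m * n / 12 *
      ((m + n + 1) - sum(tie_tab^3 - tie_tab) / ((m + n) * (m + n - 1)))
    sigma <- sqrt(sigma2)
    p_le <- stats::pnorm((w - mu + 0.5) / sigma)
    p_ge <- stats::pnorm((w - mu - 0.5) / sigma, lower.tail = FALSE)
  }
  switch(alternative,
         less = p_le,
         greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

#' Evaluate a prioritized gene set against random sets on GWA p-values
#'
#' The p-value distribution of the top `j` ranked genes (restricted to
#' genes with a GWA signal) is compared with `n_random` random gene sets
#' of the same size drawn from the GWA gene universe; a random set counts
#' as beaten when the one-sided rank-sum test finds the prioritized
#' p-values significantly smaller at level `alpha`.  The whole procedure
#' is repeated `repeats` times to attach a standard deviation to the count.
#'
#' @param ranking A `ranked_gene_list` (or character vector in rank order).
#' @param gwa A `gwa_gene_table` from [map_snps_to_genes()].
#' @param j Size of the prioritized set (top-j of the ranking).
#' @param n_random Random sets per repeat (default 1000).
#' @param repeats Number of repeats (default 10).
#' @param alpha Significance level for each comparison (default 0.05).
#' @param alternative Test side (default `"less"`).
#' @param seed Optional integer seed governing the whole evaluation;
#'   repeat r uses an independent derived stream.
#' @return List with `mean`, `sd`, `counts` (per repeat), `n_random`,
#'   `set_size` (prioritized genes found in the GWA table).
#' @export
evaluate_prioritized_set <- function(ranking, gwa, j, n_random = 1000L,
                                     repeats = 10L, alpha = 0.05,
                                     alternative = "less", seed = NULL) {
  stopifnot(n_random >= 1L, repeats >= 1L, alpha > 0, alpha < 1)
  genes <- if (is.data.frame(ranking)) ranking$gene else as.character(ranking)
  if (j < 1 || j > length(genes)) stop("j must index into the ranking")
  universe <- gwa$gene
  if (j > length(universe))
    stop("prioritized set size exceeds the GWA gene universe")
  top <- intersect(genes[seq_len(j)], universe)
  if (!length(top))
    stop("no prioritized gene carries a GWA p-value")
  k <- length(top)
  p_lookup <- stats::setNames(gwa$p, gwa$gene)
  x <- unname(p_lookup[top])
  counts <- integer(repeats)
  for (r in seq_len(repeats)) {
    if (!is.null(seed)) set.seed(derive_seed(seed, r))
    hits <- 0L
    for (b in seq_len(n_random)) {
      y <- unname(p_lookup[sample(universe, k)])
      if (wilcoxon_rank_sum(x, y, alternative = alternative) < alpha)
        hits <- hits + 1L
    }
    counts[r] <- hits
  }
  list(mean = mean(counts),
       sd = if (repeats > 1L) stats::sd(counts) else 0,
       counts = counts,
       n_random = as.integer(n_random), set_size = k)
}

# Derived sub-stream seed: deterministic, stays within 32-bit integers.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 + 97561 * as.numeric(k)) %%
               2147483647)
}
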