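#' Select the prioritized gene list at a combined-score cutoff
#'
#' @param scores Named numeric vector of combined scores (gene -> score),
#'   or a `ranked_gene_list`.
#' @param cutoff Combined-score cutoff (genes with score >= cutoff are
#'   kept; the published list used 15).
#' @return Data frame `gene`, `combined_score`, descending score with ties
#'   broken by ascending gene identifier.
#' @export
select_depgenes <- function(scores, cutoff = 15) {
  stopifnot(cutoff >= 0)
  if (is.data.frame(scores))
    scores <- stats::setNames(scores$combined_score, scores$gene)
  keep <- scores >= cutoff
  out <- data.frame(gene = names(scores)[keep],
                    combined_score = unname(scores[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$combined_score, out$gene, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score-separation diagnostics for choosing the cutoff
#'
#' The cutoff separating the prioritized list from the bulk is chosen where
#' the combined-score distributions of the core genes and of all candidates
#' separate most cleanly.  For each candidate cutoff `c` this reports the
#' fraction of core genes scoring >= c, the fraction of all candidates
#' scoring >= c, and their difference (a Youden-style separation index);
#' the suggested cutoff maximizes the separation, smallest `c` on ties.
#'
#' @param core_scores Combined scores of the core genes.
#' @param all_scores Combined scores of all candidate genes.
#' @param grid Candidate cutoffs (default: all distinct observed scores).
#' @return List with `diagnostics` (data frame `cutoff`, `core_fraction`,
#'   `candidate_fraction`, `separation`) and `suggested` (the cutoff).
#' @export
suggest_cutoff <- function(core_scores, all_scores, grid = NULL) {
  core_scores <- as.numeric(core_scores)
  all_scores <- as.numeric(all_scores)
  if (!length(core_scores) || !length(all_scores))
    stop("score sets must be non-empty")
  if (is.null(grid)) grid <- sort(unique(all_scores))
  frac_ge <- function(v, c) mean(v >= c)
  diag <- data.frame(
    cutoff = grid,
    core_fraction = vapply(grid, function(c) frac_ge(core_scores, c), 1),
    candidate_fraction = vapply(grid, function(c) frac_ge(all_scores, c), 1))
  diag$separation <- diag$core_fraction - diag$candidate_fraction
  best <- which(diag$separation == max(diag$separation))
  suggested <- min(diag$cutoff[best])
  list(diagnostics = diag, suggested = suggested)
}

#' Rank stability across weight matrices
#'
#' Spearman rank correlations (mid-ranks for ties) between the combined
#' score rankings produced by each pair of weight matrices over the shared
#' gene universe.  High average correlation indicates the prioritized list
#' is robust to the exact choice among qualifying matrices.
#'
#' @param matrices List of weight vectors (length >= 2) or an integer
#'   matrix with one weight vector per row.
#' @param E An [evidence_matrix()].
#' @param pre Pre-weight vector.
#' @return List with `correlations` (symmetric matrix, rows/cols labelled
#'   by the bracket form of each weight vector) and `mean` (off-diagonal
#'   mean).
#' @export
rank_correlation <- function(matrices, E, pre = default_preweight()) {
  if (is.matrix(matrices))
    matrices <- lapply(seq_len(nrow(matrices)), function(i) matrices[i, ])
  if (length(matrices) < 2L)
    stop("rank correlation needs at least 2 weight matrices")
  sc <- vapply(matrices, function(W) combined_scores(E, W, pre),
               numeric(nrow(E)))
  rho <- stats::cor(sc, method = "spearman")
  labels <- vapply(matrices, format_weights, character(1))
  dimnames(rho) <- list(labels, labels)
  list(correlations = rho, mean = mean(rho[lower.tri(rho)]))
}

#' Compare prioritized lists under two alternative core gene sets
#'
#' Runs the core-gene stage of the weight-matrix search separately under
#' each core set, takes each search's best matrix (smallest position j,
#' then l, then lexicographically smallest weights), selects the
#' cutoff-based gene list under each, and reports the overlap.  Genes
#' selected only under the second core set are additionally scored with
#' the first core set's optimal matrix, showing how far below the cutoff
#' they fall there.
#'
#' @param E An [evidence_matrix()].
#' @param core_a,core_b Two [core_gene_set()]s contained in `E`.
#' @param pre Pre-weight vector.
#' @param grid Weight grid as in [select_matrices()].
#' @param phi,eta Selection thresholds as in [select_matrices()].
#' @param cutoff Combined-score cutoff for both lists.
#' @return List with `depgenes_a`, `depgenes_b`, `overlap` (gene vector),
#'   `n_overlap`, `only_b_mean_score_under_a`, `matrix_a`, `matrix_b`.
#' @export
compare_core_sets <- function(E, core_a, core_b, pre = default_preweight(),
                              grid = 4L, phi = 0.9, eta = 0.05, cutoff = 15) {
  if (is.matrix(grid) && nrow(grid) == 0L) stop("empty weight grid")
  pick <- function(core) {
    res <- select_matrices(E, core, pre = pre, phi = phi, eta = eta,
                           grid = grid)
    cand <- res[res$passed, , drop = FALSE]
    if (!nrow(cand)) cand <- res   # fall back to best near-miss
    ord <- do.call(order, c(unname(cand[c("position_j", "position_l",
                                          paste0("w", 1:7))]),
                            list(method = "radix")))
    as.integer(cand[ord[1L], paste0("w", 1:7)])
  }
  W_a <- pick(core_a)
  W_b <- pick(core_b)
  dep_a <- select_depgenes(combined_scores(E, W_a, pre), cutoff)
  dep_b <- select_depgenes(combined_scores(E, W_b, pre), cutoff)
  overlap <- intersect(dep_a$gene, dep_b$gene)
  only_b <- setdiff(dep_b$gene, dep_a$gene)
  sc_a <- combined_scores(E, W_a, pre)
  list(depgenes_a = dep_a, depgenes_b = dep_b, overlap = overlap,
       n_overlap = length(overlap),
       only_b_mean_score_under_a =
         if (length(only_b)) mean(sc_a[only_b]) else NA_real_,
       matrix_a = W_a, matrix_b = W_b)
}
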