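#' Run the full prioritization pipeline
#'
#' End-to-end orchestration of one study: evaluate the weight grid against
#' the core gene set, keep the matrices whose core-gene positions pass the
#' phi/eta criterion (plus any hard position criteria), evaluate the best
#' survivors against the GWA p-values by random-set comparison, pick the
#' optimal weight matrix, and select the final prioritized gene list at a
#' combined-score cutoff.
#'
#' Survivors are ordered by (position j, position l, lexicographic weights)
#' and only the first `n_eval` are GWA-evaluated, since random-set
#' evaluation is the expensive step.  The optimal matrix maximizes the
#' evaluation mean, with ties broken by smaller position j, then smaller
#' position l, then lexicographically smallest weights.
#'
#' @param E An [evidence_matrix()].
#' @param core A [core_gene_set()] contained in `E`.
#' @param gwa A `gwa_gene_table` from [map_snps_to_genes()].
#' @param pre Pre-weight vector.
#' @param phi,eta Core-gene selection thresholds (see [select_matrices()]).
#' @param grid Weight grid: integer `d` (full pool `{1..d}^7`) or a matrix
#'   of candidate vectors.
#' @param max_j,max_l Hard position criteria (default off).
#' @param n_eval Number of top survivors to GWA-evaluate.
#' @param n_random,repeats,alpha Random-set evaluation parameters (see
#'   [evaluate_prioritized_set()]).
#' @param cutoff Combined-score cutoff for the final list; `NULL` asks
#'   [suggest_cutoff()] for the separation-maximizing cutoff.
#' @param seed Integer seed for the random-set draws.
#' @return List of class `depgene_run`: `selection` (all grid results),
#'   `survivors`, `evaluations`, `optimal_matrix`, `positions`, `scores`,
#'   `cutoff`, `depgenes`, `config`.
#' @export
run_prioritization <- function(E, core, gwa, pre = default_preweight(),
                               phi = 0.9, eta = 0.05, grid = 4L,
                               max_j = Inf, max_l = Inf, n_eval = 8L,
                               n_random = 1000L, repeats = 10L,
                               alpha = 0.05, cutoff = NULL, seed = 1L) {
  sel <- select_matrices(E, core, pre = pre, phi = phi, eta = eta,
                         grid = grid, max_j = max_j, max_l = max_l)
  wcols <- paste0("w", 1:7)
  surv <- sel[sel$passed, , drop = FALSE]
  if (!nrow(surv)) {
    near <- sel[order(sel$position_j, sel$position_l), , drop = FALSE]
    near <- utils::head(near, 5L)
    stop("no weight matrix passed the core-gene criteria (threshold rank ",
         attr(sel, "threshold"), "); best near-misses:\n",
         paste(sprintf("  %s j=%d l=%d",
                       apply(near[wcols], 1, format_weights),
                       near$position_j, near$position_l),
               collapse = "\n"))
  }
  ord <- do.call(order, c(unname(surv[c("position_j", "position_l", wcols)]),
                          list(method = "radix")))
  surv <- surv[ord, , drop = FALSE]
  rownames(surv) <- NULL
  eval_set <- utils::head(surv, n_eval)

  evals <- lapply(seq_len(nrow(eval_set)), function(i) {
    W <- as.integer(eval_set[i, wcols])
    ranking <- rank_genes(E, W, pre, core = core)
    ev <- evaluate_prioritized_set(ranking, gwa, j = eval_set$position_j[i],
                                   n_random = n_random, repeats = repeats,
                                   alpha = alpha,
                                   seed = derive_seed(seed, i))
    data.frame(matrix = format_weights(W), t(W),
               position_j = eval_set$position_j[i],
               position_l = eval_set$position_l[i],
               mean = ev$mean, sd = ev$sd, set_size = ev$set_size)
  })
  evals <- do.call(rbind, evals)
  names(evals)[2:8] <- wcols

  best <- do.call(order, c(list(-evals$mean, evals$position_j,
                                evals$position_l),
                           unname(evals[wcols]), list(method = "radix")))[1L]
  W_opt <- as.integer(evals[best, wcols])
  scores <- combined_scores(E, W_opt, pre)
  if (is.null(cutoff)) {
    cutoff <- suggest_cutoff(scores[as.character(core)], scores)$suggested
  }
  structure(list(selection = sel, survivors = surv, evaluations = evals,
                 optimal_matrix = W_opt,
                 positions = list(position_j = evals$position_j[best],
                                  position_l = evals$position_l[best]),
                 scores = scores, cutoff = cutoff,
                 depgenes = select_depgenes(scores, cutoff),
                 config = list(phi = phi, eta = eta,
                               grid = if (is.matrix(grid)) "custom" else grid,
                               max_j = max_j, max_l = max_l, n_eval = n_eval,
                               n_random = n_random, repeats = repeats,
                               alpha = alpha, seed = seed)),
            class = "depgene_run")
}

#' @export
print.depgene_run <- function(x, ...) {
  cat("Prioritization run\n")
  cat(sprintf("  matrices passing core-gene criteria: %d of %d\n",
              nrow(x$survivors), nrow(x$selection)))
  cat(sprintf("  optimal weight matrix: %s (mean %.1f of %d random sets)\n",
              format_weights(x$optimal_matrix),
              x$evaluations$mean[x$evaluations$matrix ==
                                   format_weights(x$optimal_matrix)][1],
              x$config$n_random))
  cat(sprintf("  cutoff %.3g -> %d prioritized genes\n",
              x$cutoff, nrow(x$depgenes)))
  invisible(x)
}
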