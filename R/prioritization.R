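#' Combined evidence score for one gene
#'
#' The combined score is `sum_i preWeight_i * S_i * W_i` over the seven
#' sources: per-source scores adjusted by the fixed pre-weights and by the
#' candidate integer weight vector under evaluation.
#'
#' @param S Numeric vector of 7 per-source scores.
#' @param W Integer weight vector of length 7 (entries >= 1).
#' @param pre Pre-weight vector of length 7 (default [default_preweight()]).
#' @return A single non-negative number.
#' @export
combined_score <- function(S, W, pre = default_preweight()) {
  if (length(S) != 7L || length(W) != 7L || length(pre) != 7L)
    stop("S, W and preWeight must all have length 7")
  validate_weight_vector(W)
  sum(as.numeric(pre) * as.numeric(S) * as.numeric(W))
}

#' Combined scores for every gene in an evidence matrix
#'
#' @param E An [evidence_matrix()].
#' @param W Integer weight vector of length 7.
#' @param pre Pre-weight vector of length 7.
#' @return Named numeric vector of combined scores (one per gene).
#' @export
combined_scores <- function(E, W, pre = default_preweight()) {
  validate_weight_vector(W)
  drop(unclass(E) %*% (as.numeric(pre) * as.numeric(W)))
}

validate_weight_vector <- function(W) {
  W <- as.numeric(W)
  if (anyNA(W) || any(W < 1) || any(W != floor(W)))
    stop("weight vectors must be integers >= 1")
  invisible(W)
}

#' Size of the weight-vector pool
#'
#' @param n_sources Number of evidence sources N.
#' @param d Number of weight levels (weights run 1..d; default N + 1).
#' @return `d ^ n_sources` as a double.
#' @export
n_weight_vectors <- function(n_sources = 7L, d = n_sources + 1L) {
  stopifnot(n_sources >= 1L, d >= 1L)
  d^n_sources
}

#' Materialize a block of the lexicographic weight-vector pool
#'
#' The pool is every vector in `{1..d}^N` in lexicographic order (last
#' source varies fastest).  Blocks let the full pool (8^7 = 2,097,152
#' vectors by default) be streamed through [select_matrices()] in bounded
#' memory.
#'
#' @param from 1-based index of the first vector in the block.
#' @param size Number of vectors (truncated at the end of the pool).
#' @param n_sources Number of sources N.
#' @param d Number of weight levels.
#' @return Integer matrix with `size` rows and `n_sources` columns.
#' @export
weight_vector_block <- function(from, size, n_sources = 7L, d = n_sources + 1L) {
  total <- n_weight_vectors(n_sources, d)
  if (from < 1 || from > total) stop("block start outside the pool")
  size <- min(size, total - from + 1)
  idx <- (from - 1) + seq_len(size) - 1  # 0-based pool indices
  out <- matrix(0L, nrow = size, ncol = n_sources)
  rem <- idx
  for (j in rev(seq_len(n_sources))) {   # last source is the fastest digit
    out[, j] <- as.integer(rem %% d) + 1L
    rem <- rem %/% d
  }
  out
}

#' Stream the whole weight-vector pool through a callback
#'
#' @param fun Function called once per block with the integer matrix of
#'   weight vectors; its return values are collected in a list.
#' @param n_sources,d Pool dimensions as in [weight_vector_block()].
#' @param block_size Vectors per block.
#' @return List of `fun`'s return values (one per block), invisibly.
#' @export
enumerate_weight_vectors <- function(fun, n_sources = 7L, d = n_sources + 1L,
                                     block_size = 65536L) {
  total <- n_weight_vectors(n_sources, d)
  out <- list()
  from <- 1
  while (from <= total) {
    blk <- weight_vector_block(from, block_size, n_sources, d)
    out[[length(out) + 1L]] <- fun(blk)
    from <- from + nrow(blk)
  }
  invisible(out)
}

#' Rank genes by combined score
#'
#' Candidate genes and core genes are ranked together in one merged list
#' (core genes are already part of the evidence universe, so nothing is
#' double-counted).  Ties are broken by ascending gene identifier so the
#' ranking is deterministic.
#'
#' @param E An [evidence_matrix()].
#' @param W Weight vector of length 7.
#' @param pre Pre-weight vector.
#' @param core Optional [core_gene_set()]; every core gene must be present
#'   in `E`.
#' @return Data frame `gene`, `combined_score`, `rank` in descending score
#'   order; class `ranked_gene_list`.
#' @export
rank_genes <- function(E, W, pre = default_preweight(), core = NULL) {
  if (!is.null(core)) {
    missing <- setdiff(as.character(core), rownames(E))
    if (length(missing))
      stop("core genes absent from the evidence matrix: ",
           paste(missing, collapse = ", "))
  }
  cs <- combined_scores(E, W, pre)
  ord <- order(-cs, names(cs), method = "radix")
  out <- data.frame(gene = names(cs)[ord], combined_score = unname(cs)[ord],
                    rank = seq_along(cs), stringsAsFactors = FALSE)
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}

#' Positions of the core genes in a ranking
#'
#' `position_j` is the rank of the ceiling(phi * K)-th core gene counted
#' from the top of the merged ranking; `position_l` is the rank of the last
#' core gene.  A weight matrix that concentrates the core set near the top
#' yields small `j` and `l`.
#'
#' @param ranking A `ranked_gene_list` from [rank_genes()], or a character
#'   vector of genes in rank order.
#' @param core A [core_gene_set()] fully contained in the ranking.
#' @param phi Proportion of core genes required near the top, in (0, 1].
#' @return List with `position_j`, `position_l` and `m` (= ceiling(phi*K)).
#' @export
core_gene_positions <- function(ranking, core, phi = 0.9) {
  if (phi <= 0 || phi > 1) stop("phi must lie in (0, 1]")
  genes <- if (is.data.frame(ranking)) ranking$gene else as.character(ranking)
  pos <- match(as.character(core), genes)
  if (anyNA(pos))
    stop("core genes missing from the ranking")
  pos <- sort(pos)
  m <- ceiling(phi * length(core))
  list(position_j = pos[m], position_l = pos[length(pos)], m = m)
}

#' Evaluate candidate weight matrices against the core gene set
#'
#' For each candidate weight vector the genes are ranked by combined score
#' and the core-gene positions computed; a matrix passes when the
#' ceiling(phi*K)-th core gene sits within the top ceiling(eta * n_genes)
#' of the merged ranking.  Optional hard criteria on the positions
#' (`max_j`, `max_l`) are applied on top, mirroring fixed rank thresholds
#' used at full data scale.
#'
#' @param E An [evidence_matrix()].
#' @param core A [core_gene_set()] contained in `E`.
#' @param pre Pre-weight vector.
#' @param phi Proportion of core genes, in (0, 1].
#' @param eta Proportion of candidate genes, in (0, 1).
#' @param grid Either an integer matrix of candidate weight vectors (one
#'   per row) or a single integer `d`, meaning the full pool `{1..d}^7`
#'   streamed in blocks.
#' @param max_j,max_l Hard position criteria (default `Inf` = off).
#' @param block_size Vectors per streamed block when `grid` is `d`.
#' @return Data frame with columns `w1..w7`, `position_j`, `position_l`,
#'   `passed`.
#' @export
select_matrices <- function(E, core, pre = default_preweight(), phi = 0.9,
                            eta = 0.05, grid = 4L, max_j = Inf, max_l = Inf,
                            block_size = 8192L) {
  if (eta <= 0 || eta >= 1) stop("eta must lie in (0, 1)")
  missing <- setdiff(as.character(core), rownames(E))
  if (length(missing))
    stop("core genes absent from the evidence matrix: ",
         paste(missing, collapse = ", "))
  n_genes <- nrow(E)
  threshold <- ceiling(eta * n_genes)
  m <- ceiling(phi * length(core))
  genes <- rownames(E)
  core_idx <- match(as.character(core), genes)
  # tie order: descending score, then ascending gene id; precompute the
  # identifier order once so per-matrix work is a single stable sort
  id_rank <- match(genes, sort(genes, method = "radix"))
  Emat <- unclass(E)

  eval_block <- function(Wblk) {
    eff <- t(Wblk) * as.numeric(pre)          # 7 x m effective weights
    sc <- Emat %*% eff                        # genes x m combined scores
    jl <- matrix(0L, nrow = ncol(sc), ncol = 2L)
    for (k in seq_len(ncol(sc))) {
      ord <- order(-sc[, k], id_rank, method = "radix")
      pos <- sort.int(match(core_idx, ord))
      jl[k, ] <- c(pos[m], pos[length(pos)])
    }
    cbind(Wblk, jl)
  }

  res <- if (is.matrix(grid)) {
    apply(grid, 1, validate_weight_vector)
    if (ncol(grid) != ncol(E)) stop("grid vectors must have length 7")
    eval_block(grid)
  } else {
    do.call(rbind, enumerate_weight_vectors(eval_block, n_sources = ncol(E),
                                            d = as.integer(grid),
                                            block_size = block_size))
  }
  out <- as.data.frame(res)
  names(out) <- c(paste0("w", seq_len(ncol(E))), "position_j", "position_l")
  out$passed <- out$position_j <= threshold &
    out$position_j <= max_j & out$position_l <= max_l
  attr(out, "threshold") <- threshold
  attr(out, "m") <- m
  out
}

#' Format a weight vector as the conventional bracket string
#'
#' @param W Integer weight vector.
#' @return A string like `"[2,1,1,8,1,1,7]"`.
#' @export
format_weights <- function(W) {
  paste0("[", paste(as.integer(W), collapse = ","), "]")
}
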