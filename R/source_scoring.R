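#' Default association scoring table
#'
#' Association-study evidence is scored 0-4 from two criteria: how many
#' studies examined the gene, and what proportion reported a positive
#' association.  Crossing the two damps extreme positive proportions that
#' arise when only one or two studies exist (a guard against publication
#' bias); the maximum score requires many studies with a high positive rate.
#'
#' @param path Optional YAML file overriding the packaged table; it must
#'   contain `study_bands` (lower edges, starting at 0), `proportion_bands`
#'   (lower edges, starting at 0) and a `scores` matrix, monotone
#'   non-decreasing along both axes.
#' @return A list of class `association_table` with elements `study_bands`,
#'   `proportion_bands`, `scores`.
#' @export
default_association_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "association_score_table.yaml",
                        package = "depgenes", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  sb <- as.numeric(y$study_bands)
  pb <- as.numeric(y$proportion_bands)
  sc <- do.call(rbind, lapply(y$scores, as.numeric))
  if (nrow(sc) != length(sb) || ncol(sc) != length(pb))
    stop("association table dimensions do not match its bands")
  if (is.unsorted(sb, strictly = TRUE) || is.unsorted(pb, strictly = TRUE))
    stop("association table bands must be strictly increasing")
  if (any(apply(sc, 2, diff) < 0) || any(apply(sc, 1, diff) < 0))
    stop("association scoring table must be monotone in both criteria")
  structure(list(study_bands = sb, proportion_bands = pb, scores = sc),
            class = "association_table")
}

#' Score association-study evidence
#'
#' @param n_studies Number of association studies for the gene.
#' @param n_positive Number of those reporting a positive association
#'   (`n_positive <= n_studies`).
#' @param table An `association_table` (default packaged table).
#' @return Integer score in 0..4; 0 whenever `n_studies` is 0.
#' @export
score_association <- function(n_studies, n_positive,
                              table = default_association_table()) {
  stopifnot(length(n_studies) == length(n_positive))
  if (any(n_studies < 0 | n_positive < 0 | n_positive > n_studies, na.rm = TRUE))
    stop("need 0 <= n_positive <= n_studies")
  prop <- ifelse(n_studies > 0, n_positive / n_studies, 0)
  si <- findInterval(n_studies, table$study_bands)
  pi <- findInterval(prop, table$proportion_bands)
  out <- table$scores[cbind(si, pi)]
  out[n_studies == 0] <- 0
  out
}

#' Score linkage evidence
#'
#' A gene in a linkage region scores by the stronger of the region's LOD
#' score and -log10 p (when only p-values were reported).  Signals below
#' LOD 1 carry no evidence; above 1 the score is the statistic itself, so
#' one extra LOD unit adds one score unit.
#'
#' @param lod LOD score (`NA` if unavailable).
#' @param neglog10p -log10 p-value (`NA` if unavailable).
#' @return Numeric score, 0 when the best statistic is below 1.
#' @export
score_linkage <- function(lod = NA_real_, neglog10p = NA_real_) {
  n <- max(length(lod), length(neglog10p))
  lod <- rep_len(as.numeric(lod), n)
  neglog10p <- rep_len(as.numeric(neglog10p), n)
  if (any(is.na(lod) & is.na(neglog10p)))
    stop("linkage evidence needs at least one of LOD or -log10 p")
  if (any(c(lod, neglog10p) < 0, na.rm = TRUE))
    stop("linkage statistics must be >= 0")
  v <- pmax(lod, neglog10p, na.rm = TRUE)
  ifelse(v < 1, 0, v)
}

#' Score differential-expression evidence
#'
#' Genes extracted at p < 0.05 from an expression study score -log10 p;
#' genes failing the extraction filter carry no expression evidence.
#'
#' @param p_value Expression p-value in (0, 1].
#' @param p_max Extraction threshold (default 0.05).
#' @return Numeric score, 0 for `p_value >= p_max`.
#' @export
score_expression <- function(p_value, p_max = 0.05) {
  p_value <- as.numeric(p_value)
  if (any(is.na(p_value) | p_value <= 0 | p_value > 1))
    stop("expression p-values must lie in (0, 1]")
  ifelse(p_value < p_max, -log10(p_value), 0)
}

#' Default literature keyword vocabularies
#'
#' Six depression keywords per species: diagnostic/scale terms for human
#' literature, behavioural-paradigm terms for animal-model literature.
#'
#' @param species `"human"` or `"animal"`.
#' @return Character vector of 6 keywords.
#' @export
literature_vocabulary <- function(species = c("human", "animal")) {
  switch(match.arg(species),
    human = c("depression", "depressive disorder", "unipolar disorder",
              "dysthymia", "major depression", "major depressive disorder"),
    animal = c("forced swim test", "tail suspension test",
               "elevated plus maze", "novelty induced hypophagia",
               "olfactory bulbectomy", "open field test"))
}

#' Score literature co-occurrence evidence
#'
#' One point per distinct vocabulary keyword that co-occurs with the gene
#' in at least one citation, so scores run from 0 to the vocabulary size
#' (6 by default).
#'
#' @param keywords_hit Character vector of distinct keywords hit.
#' @param vocabulary Allowed keywords (default human vocabulary).
#' @return Integer score `length(unique(keywords_hit))`.
#' @export
score_literature <- function(keywords_hit,
                             vocabulary = literature_vocabulary("human")) {
  keywords_hit <- unique(as.character(keywords_hit))
  keywords_hit <- keywords_hit[nzchar(keywords_hit)]
  bad <- setdiff(keywords_hit, vocabulary)
  if (length(bad))
    stop("keywords outside the vocabulary: ", paste(bad, collapse = ", "))
  length(keywords_hit)
}

#' Score pathway-membership evidence
#'
#' Pathway membership scores by disease mechanism: 3 for monoamine
#' deficiency, 2 for the hypothalamic-pituitary-adrenal axis, 1 for other
#' proposed mechanisms.  A gene in several mechanisms takes the greatest.
#'
#' @param mechanisms Character vector drawn from `"monoamine"`, `"hpa_axis"`,
#'   `"other"` (possibly empty).
#' @return Integer score in 0..3.
#' @export
score_pathway <- function(mechanisms) {
  mechanisms <- as.character(mechanisms)
  mechanisms <- mechanisms[nzchar(mechanisms)]
  if (!length(mechanisms)) return(0L)
  pts <- c(monoamine = 3L, hpa_axis = 2L, other = 1L)
  bad <- setdiff(mechanisms, names(pts))
  if (length(bad))
    stop("unknown pathway mechanisms: ", paste(bad, collapse = ", "))
  max(pts[mechanisms])
}

#' Build an evidence matrix from raw per-source evidence
#'
#' Applies the five scoring rules (expression and literature separately for
#' human and animal inputs) and assembles the genes x 7 score matrix over
#' the union of genes seen in any source.  Sources without evidence for a
#' gene score 0.
#'
#' @param association Data frame `gene`, `n_studies`, `n_positive`, or NULL.
#' @param linkage Data frame `gene`, `lod`, `neglog10p` (either may be NA),
#'   or NULL.
#' @param expression_human,expression_animal Data frames `gene`, `p_value`,
#'   or NULL.
#' @param literature_human,literature_animal Data frames `gene`, `keywords`
#'   (comma-separated keyword hits), or NULL.
#' @param pathway Data frame `gene`, `mechanisms` (comma-separated), or NULL.
#' @param association_table Scoring table for [score_association()].
#' @return An [evidence_matrix()]; zero rows if all inputs are NULL/empty.
#' @export
build_evidence_matrix <- function(association = NULL, linkage = NULL,
                                  expression_human = NULL,
                                  literature_human = NULL, pathway = NULL,
                                  expression_animal = NULL,
                                  literature_animal = NULL,
                                  association_table = default_association_table()) {
  split_csv <- function(x) {
    x <- as.character(x)
    lapply(strsplit(ifelse(is.na(x), "", x), ","), trimws)
  }
  per_source <- list(
    association = if (!is.null(association) && nrow(association))
      stats::setNames(score_association(association$n_studies,
                                        association$n_positive,
                                        association_table),
                      toupper(association$gene)),
    linkage = if (!is.null(linkage) && nrow(linkage))
      stats::setNames(score_linkage(linkage$lod, linkage$neglog10p),
                      toupper(linkage$gene)),
    expression_human = if (!is.null(expression_human) && nrow(expression_human))
      stats::setNames(score_expression(expression_human$p_value),
                      toupper(expression_human$gene)),
    literature_human = if (!is.null(literature_human) && nrow(literature_human))
      stats::setNames(vapply(split_csv(literature_human$keywords),
                             score_literature, numeric(1),
                             vocabulary = literature_vocabulary("human")),
                      toupper(literature_human$gene)),
    pathway = if (!is.null(pathway) && nrow(pathway))
      stats::setNames(vapply(split_csv(pathway$mechanisms),
                             function(m) as.numeric(score_pathway(m)),
                             numeric(1)),
                      toupper(pathway$gene)),
    expression_animal = if (!is.null(expression_animal) && nrow(expression_animal))
      stats::setNames(score_expression(expression_animal$p_value),
                      toupper(expression_animal$gene)),
    literature_animal = if (!is.null(literature_animal) && nrow(literature_animal))
      stats::setNames(vapply(split_csv(literature_animal$keywords),
                             score_literature, numeric(1),
                             vocabulary = literature_vocabulary("animal")),
                      toupper(literature_animal$gene))
  )
  genes <- sort(unique(unlist(lapply(per_source, names))))
  if (is.null(genes)) genes <- character(0)
  sc <- matrix(0, nrow = length(genes), ncol = 7L,
               dimnames = list(genes, evidence_sources()))
  for (s in evidence_sources()) {
    v <- per_source[[s]]
    if (!is.null(v)) {
      if (anyDuplicated(names(v)))
        stop("duplicate gene in raw ", s, " evidence")
      sc[names(v), s] <- unname(v)
    }
  }
  evidence_matrix(sc)
}

#' Read raw per-source evidence files from a directory
#'
#' Expects the TSV layout written by [write_synthetic_inputs()]:
#' `association.tsv` (gene, n_studies, n_positive), `linkage.tsv`
#' (gene, lod, neglog10p), `expression_human.tsv` / `expression_animal.tsv`
#' (gene, p_value), `literature_human.tsv` / `literature_animal.tsv`
#' (gene, keywords), `pathway.tsv` (gene, mechanisms).  Missing files mean
#' no evidence from that source.
#'
#' @param dir Directory holding the files.
#' @param association_table Scoring table for [score_association()].
#' @return An [evidence_matrix()].
#' @export
read_raw_evidence <- function(dir, association_table = default_association_table()) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p))
      utils::read.delim(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    else NULL
  }
  build_evidence_matrix(
    association = rd("association.tsv"),
    linkage = rd("linkage.tsv"),
    expression_human = rd("expression_human.tsv"),
    literature_human = rd("literature_human.tsv"),
    pathway = rd("pathway.tsv"),
    expression_animal = rd("expression_animal.tsv"),
    literature_animal = rd("literature_animal.tsv"),
    association_table = association_table)
}
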