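#' Construct a tissue x gene presence matrix
#'
#' Binary indicators of whether each gene is expressed in each tissue
#' (rows = tissues, columns = genes).
#'
#' @param M Matrix of 0/1 indicators with tissue rownames and gene colnames.
#' @return Integer matrix of class `tissue_expression_matrix`.
#' @export
tissue_expression_matrix <- function(M) {
  M <- as.matrix(M)
  if (is.null(rownames(M)) || is.null(colnames(M)))
    stop("tissue matrix needs tissue rownames and gene colnames")
  colnames(M) <- toupper(colnames(M))
  if (anyDuplicated(rownames(M)) || anyDuplicated(colnames(M)))
    stop("tissue and gene labels must be unique")
  if (!all(M %in% c(0, 1))) stop("presence indicators must be 0 or 1")
  storage.mode(M) <- "integer"
  structure(M, class = c("tissue_expression_matrix", "matrix", "array"))
}

#' Read a tissue presence matrix from TSV
#'
#' Rows are tissues, columns genes, cells 0/1; first column holds the
#' tissue labels.
#'
#' @param path Path to the TSV file.
#' @return A [tissue_expression_matrix()].
#' @export
read_tissue_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  tissue_expression_matrix(as.matrix(df))
}

#' Per-tissue expression proportion of a gene set
#'
#' For each tissue, the fraction of the gene set's matrix-present genes
#' with presence indicator 1.  Genes absent from the matrix are excluded
#' from the denominator.
#'
#' @param M A [tissue_expression_matrix()].
#' @param geneset Character vector of gene symbols.
#' @return Named numeric vector, one proportion per tissue.
#' @export
expression_proportions <- function(M, geneset) {
  geneset <- unique(toupper(as.character(geneset)))
  found <- intersect(geneset, colnames(M))
  if (!length(found))
    stop("none of the genes appear in the tissue matrix")
  rowMeans(unclass(M)[, found, drop = FALSE])
}

#' Compare the tissue expression profiles of two gene sets
#'
#' Computes per-tissue expression proportions for both sets and tests the
#' paired per-tissue differences with the Wilcoxon signed-rank test (zero
#' differences dropped, mid-ranks for ties; exact null distribution for up
#' to 25 non-zero pairs without ties, normal approximation otherwise).
#' When all differences are zero the test is degenerate and p = 1 is
#' reported with a warning.
#'
#' @param M A [tissue_expression_matrix()].
#' @param set_a,set_b Gene sets to compare (a - b differences).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return List with `proportions` (data frame `tissue`, `prop_a`,
#'   `prop_b`, `difference`) and `p_value`.
#' @export
compare_tissue_profiles <- function(M, set_a, set_b,
                                    alternative = c("two.sided", "greater",
                                                    "less")) {
  alternative <- match.arg(alternative)
  if (nrow(M) < 6L)
    warning("fewer than 6 tissues: the signed-rank test has little power")
  pa <- expression_proportions(M, set_a)
  pb <- expression_proportions(M, set_b)
  d <- pa - pb
  props <- data.frame(tissue = rownames(M), prop_a = unname(pa),
                      prop_b = unname(pb), difference = unname(d),
                      stringsAsFactors = FALSE)
  nz <- d[d != 0]
  if (!length(nz)) {
    warning("all per-tissue differences are zero; signed-rank test is ",
            "degenerate, reporting p = 1")
    return(list(proportions = props, p_value = 1))
  }
  exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
  p <- suppressWarnings(
    stats::wilcox.test(pa, pb, paired = TRUE, alternative = alternative,
                       exact = exact, correct = TRUE)$p.value)
  list(proportions = props, p_value = p)
}
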