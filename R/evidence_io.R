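#' The seven evidence sources, in canonical order
#'
#' All evidence matrices, pre-weight vectors and weight vectors use this
#' fixed source order: association studies, linkage scans, human expression,
#' human literature, regulatory pathways, animal expression, animal
#' literature.  Weight vectors are interpreted positionally against it.
#'
#' @return Character vector of the 7 source names.
#' @export
evidence_sources <- function() {
  c("association", "linkage", "expression_human", "literature_human",
    "pathway", "expression_animal", "literature_animal")
}

#' Construct an evidence matrix
#'
#' An `evidence_matrix` is a numeric genes x 7 matrix of per-source scores
#' `S_i` (0 = no evidence), with unique upper-case gene symbols as row names
#' and [evidence_sources()] as column names.  It is the substrate of all
#' prioritization: combined scores are weighted row sums of this matrix.
#'
#' @param scores Numeric matrix, rows = genes (rownames required), columns
#'   either named by [evidence_sources()] or unnamed with exactly 7 columns.
#' @return An object of class `evidence_matrix`.
#' @export
evidence_matrix <- function(scores) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) {
    if (ncol(scores) != 7L)
      stop("evidence matrix must have exactly 7 source columns")
    colnames(scores) <- evidence_sources()
  }
  if (!identical(colnames(scores), evidence_sources()))
    stop("evidence matrix columns must be, in order: ",
         paste(evidence_sources(), collapse = ", "))
  if (is.null(rownames(scores)) && nrow(scores) > 0)
    stop("evidence matrix requires gene identifiers as row names")
  rownames(scores) <- toupper(if (is.null(rownames(scores))) character(0)
                              else rownames(scores))
  if (anyDuplicated(rownames(scores)))
    stop("duplicate gene identifiers in evidence matrix")
  storage.mode(scores) <- "double"
  if (any(!is.finite(scores)))
    stop("all evidence scores must be finite")
  if (any(scores < 0))
    stop("evidence scores must be >= 0")
  structure(scores, class = c("evidence_matrix", "matrix", "array"))
}

#' @export
print.evidence_matrix <- function(x, ...) {
  cat(sprintf("evidence_matrix: %d genes x %d sources\n", nrow(x), ncol(x)))
  print(utils::head(unclass(x)), ...)
  if (nrow(x) > 6L) cat(sprintf("... and %d more genes\n", nrow(x) - 6L))
  invisible(x)
}

#' Read an evidence score table
#'
#' Reads a tab-separated table with header `gene` followed by the seven
#' source columns.  Empty cells are scored 0 (absent evidence).  Gene
#' symbols are upper-cased; duplicated rows are collapsed when their scores
#' agree and rejected otherwise.
#'
#' @param path Path to a TSV file.
#' @param source_names Expected source columns (default [evidence_sources()]).
#' @return An [evidence_matrix()].
#' @export
read_evidence_table <- function(path, source_names = evidence_sources()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  if (ncol(df) < 1L || names(df)[1] != "gene" ||
      !identical(names(df)[-1], source_names))
    stop("malformed evidence table header in ", path,
         ": expected 'gene' followed by ", paste(source_names, collapse = ", "))
  gene <- toupper(trimws(df$gene))
  sc <- as.matrix(df[-1])
  sc[sc == ""] <- "0"
  sc <- matrix(as.numeric(sc), nrow = nrow(df),
               dimnames = list(NULL, source_names))
  if (anyNA(sc)) stop("non-numeric score cell in ", path)
  if (any(sc < 0)) stop("negative score in ", path)
  if (anyDuplicated(gene)) {
    keep <- !duplicated(gene)
    for (g in unique(gene[duplicated(gene)])) {
      rows <- sc[gene == g, , drop = FALSE]
      if (nrow(unique(rows)) > 1L)
        stop("duplicate gene ", g, " with conflicting scores in ", path)
    }
    gene <- gene[keep]
    sc <- sc[keep, , drop = FALSE]
  }
  rownames(sc) <- gene
  evidence_matrix(sc)
}

#' Write an evidence score table
#'
#' Inverse of [read_evidence_table()]: writes the TSV layout that
#' `read_evidence_table()` reads back unchanged (up to numeric formatting).
#'
#' @param E An [evidence_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence_table <- function(E, path) {
  df <- data.frame(gene = rownames(E), unclass(E), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a core gene set
#'
#' A small expert-curated list of well-supported disease genes, used as
#' positives when selecting the weight matrix.
#'
#' @param genes Character vector of gene symbols (upper-cased, de-duplicated).
#' @return Character vector of class `core_gene_set`.
#' @export
core_gene_set <- function(genes) {
  genes <- unique(toupper(trimws(as.character(genes))))
  genes <- genes[nzchar(genes)]
  if (length(genes) < 2L)
    stop("a core gene set needs at least 2 genes")
  structure(genes, class = "core_gene_set")
}

#' Read a core gene list from file
#'
#' One gene symbol per line; `#` starts a comment.
#'
#' @param path Path to a text file.
#' @return A [core_gene_set()].
#' @export
read_core_genes <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  core_gene_set(x[nzchar(x)])
}

#' Default pre-weight vector
#'
#' Per-source pre-multipliers between 0.5 and 1.5 that adjust for the unequal raw
#' score ranges of the seven sources before the integer weights are applied.
#' The packaged default is the published effective weight vector
#' (3, 1, 1.5, 4, 1, 1, 3.5) divided element-wise by the optimal weight
#' matrix `[2,1,1,8,1,1,7]`, i.e. (1.5, 1, 1.5, 0.5, 1, 1, 0.5).
#'
#' @param path Optional YAML file (source name -> value) overriding the
#'   packaged default.
#' @return Named numeric vector of length 7 in source order.
#' @export
default_preweight <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "preweight.yaml", package = "depgenes",
                        mustWork = TRUE)
  y <- yaml::read_yaml(path)
  pw <- vapply(evidence_sources(), function(s) as.numeric(y[[s]]), numeric(1))
  validate_preweight(pw)
}

validate_preweight <- function(pw) {
  pw <- as.numeric(pw)
  if (length(pw) != 7L || anyNA(pw))
    stop("preWeight must be 7 finite values")
  if (any(pw < 0.5 | pw > 1.5))
    stop("preWeight values must lie in [0.5, 1.5]")
  names(pw) <- evidence_sources()
  pw
}

#' Load the packaged DEPgenes reference table
#'
#' The published list of 169 prioritized depression genes (combined score of
#' 15 or more) with their combined scores, as a data frame sorted by
#' descending score.
#'
#' @return Data frame with columns `gene` and `combined_score`.
#' @export
load_fixture_depgenes <- function() {
  path <- system.file("extdata", "depgenes_table2.tsv", package = "depgenes",
                      mustWork = TRUE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$gene <- toupper(df$gene)
  stopifnot(!anyDuplicated(df$gene), all(df$combined_score > 0))
  df
}

#' Load the packaged 14-gene core set
#'
#' Six genes supported by an MDD association meta-analysis (APOE, DRD4,
#' GNB3, MTHFR, SLC6A3, SLC6A4) plus eight from review articles (BDNF,
#' CREB1, GRM7, HTR1A, HTR1B, HTR2A, MAOA, TPH1).
#'
#' @return A [core_gene_set()] of size 14.
#' @export
load_fixture_core_genes <- function() {
  read_core_genes(system.file("extdata", "core_genes.txt",
                              package = "depgenes", mustWork = TRUE))
}

#' Read a gene coordinate table
#'
#' Tab-separated `chrom`, `start`, `end`, `gene` with 1-based inclusive
#' coordinates.  Files whose name ends in `.bed` are interpreted as 0-based
#' half-open BED and converted (start + 1) on read.
#'
#' @param path Path to a coordinate file.
#' @return Data frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_coordinates <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("coordinate file needs 4 columns: chrom start end gene")
  names(df)[1:4] <- c("chrom", "start", "end", "gene")
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) df$start <- df$start + 1
  gene_coordinates(df$gene, df$chrom, df$start, df$end)
}

#' Construct a gene coordinate table
#'
#' @param gene Gene identifiers.
#' @param chrom Chromosome labels.
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @return Data frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
gene_coordinates <- function(gene, chrom, start, end) {
  gene <- toupper(as.character(gene))
  chrom <- as.character(chrom)
  if (any(!nzchar(chrom))) stop("empty chromosome label")
  if (any(start > end)) stop("gene start must be <= end")
  if (anyDuplicated(gene)) stop("duplicate gene in coordinate table")
  data.frame(gene = gene, chrom = chrom, start = as.numeric(start),
             end = as.numeric(end), stringsAsFactors = FALSE)
}
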