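#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix with genes in rows and
#' samples in columns, carrying its condition label as an attribute. The
#' analysis is built on Spearman rank correlations, so the expression scale
#' (counts, RPKM, log) is irrelevant and no normalisation is applied; the two
#' conditions may even be on different monotone scales.
#'
#' Missing or non-finite values are rejected outright: the downstream rank
#' correlation has no missing-data handling, and silent imputation would
#' corrupt the subsampling variance estimates.
#'
#' @param values Numeric matrix, genes x samples.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   `rownames(values)`).
#' @param sample_ids Character vector of unique sample identifiers (defaults
#'   to `colnames(values)`).
#' @param condition Condition label, e.g. a tissue name.
#' @return A numeric matrix of class `expression_matrix` with dimnames set
#'   and a `condition` attribute.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              condition = "condition") {
  values <- as.matrix(values)
  if (length(values) == 0L || nrow(values) == 0L || ncol(values) == 0L) {
    stop("expression matrix is empty", call. = FALSE)
  }
  if (!is.numeric(values)) stop("expression values must be numeric", call. = FALSE)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("gene_ids length does not match row count", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("sample_ids length does not match column count", call. = FALSE)
  }
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L) {
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]), call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  attr(values, "condition") <- as.character(condition)[1L]
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Condition label of an expression matrix
#' @param m An `expression_matrix`.
#' @return The condition label string.
#' @export
condition_label <- function(m) attr(m, "condition")

#' Read a gene-by-sample expression table
#'
#' Reads a tab-separated table with a header row of sample ids and gene ids
#' in the first column, or a GCT v1.2 file (the same table preceded by a
#' `#1.2` line, a dimensions line, and with `Name`/`Description` columns, of
#' which `Description` is dropped). Row order is preserved. Duplicate gene
#' ids, non-numeric cells and empty tables are hard errors.
#'
#' @param path Path to the file.
#' @param dialect Either `"tsv"` or `"gct"`.
#' @param condition Condition label to attach; defaults to the file name.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, dialect = c("tsv", "gct"),
                                  condition = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(condition)) {
    condition <- sub("\\.[^.]*$", "", basename(path))
  }
  skip <- 0L
  drop_desc <- FALSE
  if (dialect == "gct") {
    head2 <- readLines(path, n = 2L)
    if (length(head2) < 2L || !startsWith(head2[1L], "#1.2")) {
      stop("not a GCT v1.2 file (missing '#1.2' header): ", path, call. = FALSE)
    }
    skip <- 2L
    drop_desc <- TRUE
  }
  tab <- utils::read.delim(path, skip = skip, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) {
    stop("empty expression table: ", path, call. = FALSE)
  }
  gene_ids <- as.character(tab[[1L]])
  tab <- tab[, -1L, drop = FALSE]
  if (drop_desc && ncol(tab) >= 1L &&
      tolower(names(tab)[1L]) == "description") {
    tab <- tab[, -1L, drop = FALSE]
  }
  if (ncol(tab) == 0L) stop("empty expression table: ", path, call. = FALSE)
  sample_ids <- names(tab)
  vals <- matrix(NA_real_, nrow(tab), ncol(tab))
  for (j in seq_along(tab)) {
    col <- tab[[j]]
    if (is.character(col) || is.factor(col)) {
      num <- suppressWarnings(as.numeric(as.character(col)))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric cell at row %d (gene '%s'), column '%s'",
                     bad[1L], gene_ids[bad[1L]], sample_ids[j]), call. = FALSE)
      }
      col <- num
    }
    vals[, j] <- as.numeric(col)
  }
  expression_matrix(vals, gene_ids, sample_ids, condition)
}

#' Restrict an expression matrix to a keep-list of genes
#'
#' Typical use is restricting to protein-coding gene identifiers before
#' correlation analysis. Keeps exactly the intersection of the matrix's genes
#' with `keep_ids`, in the original row order. Identifier matching is exact
#' string match; no id mapping is attempted.
#'
#' @param m An [expression_matrix()].
#' @param keep_ids Character vector of gene ids to keep.
#' @return The filtered `expression_matrix`.
#' @export
filter_genes <- function(m, keep_ids) {
  keep_ids <- unique(as.character(keep_ids))
  if (length(keep_ids) == 0L) stop("keep_ids is empty", call. = FALSE)
  genes <- rownames(m)
  unknown <- setdiff(keep_ids, genes)
  if (length(unknown) > 0L) {
    warning(length(unknown), " keep-list id(s) not present in the matrix, ignored",
            call. = FALSE)
  }
  sel <- genes %in% keep_ids
  if (!any(sel)) {
    stop("keep-list has empty intersection with the expression matrix",
         call. = FALSE)
  }
  message(sprintf("filter_genes: kept %d of %d genes (%d dropped)",
                  sum(sel), length(genes), sum(!sel)))
  expression_matrix(unclass(m)[sel, , drop = FALSE],
                    genes[sel], colnames(m), condition_label(m))
}

#' Align two expression matrices on their shared genes
#'
#' The pairwise comparison needs a one-to-one match between the genes of the
#' two conditions: both outputs contain exactly the genes present in both
#' inputs, in the same row order (the order of appearance in `m1`). Sample
#' columns are untouched; the two conditions may have different sample counts.
#'
#' @param m1,m2 Two [expression_matrix()] objects.
#' @return A list with elements `m1` and `m2`, row-aligned.
#' @export
align_matrices <- function(m1, m2) {
  shared <- intersect(rownames(m1), rownames(m2))
  if (length(shared) == 0L) {
    stop("the two matrices share no genes", call. = FALSE)
  }
  a1 <- expression_matrix(unclass(m1)[shared, , drop = FALSE],
                          shared, colnames(m1), condition_label(m1))
  a2 <- expression_matrix(unclass(m2)[shared, , drop = FALSE],
                          shared, colnames(m2), condition_label(m2))
  list(m1 = a1, m2 = a2)
}

#' Write a typed network as edge and node attribute tables
#'
#' Writes `<prefix>_edges.tsv` with columns gene_a, gene_b, type, score,
#' rho1, rho2 (gene_a < gene_b on each row) and `<prefix>_nodes.tsv` with
#' columns gene, k, k_C, k_S, k_D, H. Both are plain TSV with headers,
#' loadable by Cytoscape's table import.
#'
#' @param net A typed network from [assemble_network()].
#' @param prefix Output path prefix.
#' @param digits Significant digits for numeric columns (default 6).
#' @return Invisibly, a named character vector with the two file paths.
#' @export
write_network_files <- function(net, prefix, digits = 6) {
  edge_path <- paste0(prefix, "_edges.tsv")
  node_path <- paste0(prefix, "_nodes.tsv")
  ed <- network_edge_table(net)
  num <- vapply(ed, is.numeric, logical(1L))
  ed[num] <- lapply(ed[num], signif, digits = digits)
  if (igraph::vcount(net) > 0L) {
    nd <- node_summaries(net)
    nd <- nd[, c("gene", "k", "k_C", "k_S", "k_D", "H")]
    nd$H <- signif(nd$H, digits)
  } else {
    nd <- data.frame(gene = character(), k = integer(), k_C = integer(),
                     k_S = integer(), k_D = integer(), H = numeric())
  }
  utils::write.table(ed, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(nd, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(edges = edge_path, nodes = node_path))
}

#' Read a typed edge table written by [write_network_files()]
#'
#' @param path Path to the `_edges.tsv` file.
#' @return A data frame of typed pairs (gene_a, gene_b, type, score, rho1,
#'   rho2), suitable for [assemble_network()].
#' @export
read_network_edges <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ed <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene_a = "character",
                                         gene_b = "character",
                                         type = "character"))
  required <- c("gene_a", "gene_b", "type", "score")
  miss <- setdiff(required, names(ed))
  if (length(miss) > 0L) {
    stop("edge table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(ed) > 0L && !all(ed$type %in% c("C", "S", "D"))) {
    stop("edge types must be C, S or D", call. = FALSE)
  }
  ed
}
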