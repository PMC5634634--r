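# shared fixture builders; everything is generated in code at test time

make_expr <- function(values, genes = NULL, samples = NULL,
                      condition = "cond") {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(values)))
  expression_matrix(values, genes, samples, condition)
}

write_expr_tsv <- function(m, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(gene = rownames(m), unclass(m), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_expr_gct <- function(m, path = tempfile(fileext = ".gct")) {
  con <- file(path, "w")
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  df <- data.frame(Name = rownames(m), Description = "na", unclass(m),
                   check.names = FALSE)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  path
}

# exhaustive oracle for the defining property of a subsample design:
# no unordered index pair may co-occur in two subsamples
max_pair_cooccurrence <- function(design) {
  cooc <- matrix(0L, design$N, design$N)
  for (s in design$subsamples) {
    p <- t(combn(sort(s), 2L))
    cooc[p] <- cooc[p] + 1L
  }
  if (length(design$subsamples) == 0L) 0L else max(cooc)
}

typed_pairs_df <- function(a, b, type, score = rep(1, length(a))) {
  data.frame(gene_a = a, gene_b = b, type = type, score = score,
             rho1 = rep(NA_real_, length(a)), rho2 = rep(NA_real_, length(a)),
             stringsAsFactors = FALSE)
}

# tiny igraph builders
graph_from_pairs <- function(a, b) {
  igraph::graph_from_data_frame(data.frame(a = a, b = b), directed = FALSE)
}
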