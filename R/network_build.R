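#' Assemble the consolidated typed co-expression network
#'
#' Builds an undirected simple `igraph` graph from a typed pair list
#' ([classify_pairs()] output or a table read back with
#' [read_network_edges()]). Edges carry `type` (C/S/D), `score` and, when
#' available, `rho1`/`rho2`; the node set is the union of edge endpoints, so
#' genes without a retained link are not nodes. Exact duplicates of a pair
#' (either orientation) collapse to one edge; duplicates with conflicting
#' types are an error, since the classifier assigns one type per pair.
#'
#' @param typed_pairs Data frame with columns `gene_a`, `gene_b`, `type`,
#'   `score` (optionally `rho1`, `rho2`).
#' @return An `igraph` object.
#' @export
assemble_network <- function(typed_pairs) {
  req <- c("gene_a", "gene_b", "type", "score")
  miss <- setdiff(req, names(typed_pairs))
  if (length(miss) > 0L) {
    stop("typed pair list missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tp <- typed_pairs
  if (nrow(tp) > 0L) {
    if (!all(tp$type %in% c("C", "S", "D"))) {
      stop("edge types must be C, S or D", call. = FALSE)
    }
    if (any(tp$gene_a == tp$gene_b)) stop("self-loop in pair list", call. = FALSE)
    pr <- canonical_pair(tp$gene_a, tp$gene_b)
    tp$gene_a <- pr$a
    tp$gene_b <- pr$b
    key <- paste(tp$gene_a, tp$gene_b, sep = "\r")
    if (anyDuplicated(key)) {
      conflict <- tapply(tp$type, key, function(t) length(unique(t)) > 1L)
      if (any(conflict)) {
        bad <- sub("\r", " - ", names(conflict)[conflict][1L])
        stop("duplicate pair with conflicting types: ", bad, call. = FALSE)
      }
      tp <- tp[!duplicated(key), , drop = FALSE]
    }
    tp <- tp[order(tp$gene_a, tp$gene_b, method = "radix"), , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(tp, directed = FALSE)
  counts <- table(factor(igraph::E(g)$type, levels = c("C", "S", "D")))
  message(sprintf("network: %d nodes, %d edges (%d C, %d S, %d D)",
                  igraph::vcount(g), igraph::ecount(g),
                  counts[["C"]], counts[["S"]], counts[["D"]]))
  g
}

#' Edge table of a typed network
#'
#' @param net An `igraph` typed network.
#' @return Data frame `gene_a`, `gene_b`, `type`, `score`, `rho1`, `rho2`
#'   with `gene_a < gene_b` on each row, sorted.
#' @export
network_edge_table <- function(net) {
  ed <- igraph::as_data_frame(net, what = "edges")
  if (nrow(ed) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      type = character(), score = numeric(),
                      rho1 = numeric(), rho2 = numeric(),
                      stringsAsFactors = FALSE))
  }
  pr <- canonical_pair(ed$from, ed$to)
  out <- data.frame(gene_a = pr$a, gene_b = pr$b, type = ed$type,
                    score = ed$score, stringsAsFactors = FALSE)
  out$rho1 <- if ("rho1" %in% names(ed)) ed$rho1 else NA_real_
  out$rho2 <- if ("rho2" %in% names(ed)) ed$rho2 else NA_real_
  out[order(out$gene_a, out$gene_b, method = "radix"), , drop = FALSE]
}

#' Node homogeneity
#'
#' For a node with `k_C`, `k_S` and `k_D` links of each type and total
#' degree `k = k_C + k_S + k_D`, the homogeneity is
#' \deqn{H = \sum_{j \in \{C,S,D\}} (k_j / k)^2.}
#' `H = 1` iff all links share one type; the floor `H = 1/3` is reached at
#' an even three-way split. Nodes with one neighbour always have `H = 1`;
#' with two neighbours, `H` is 1 or 0.5. Vectorised over nodes.
#'
#' @param k_C,k_S,k_D Per-type link counts (non-negative, not all zero).
#' @return Homogeneity in \[1/3, 1\].
#' @export
homogeneity <- function(k_C, k_S, k_D) {
  if (any(k_C < 0 | k_S < 0 | k_D < 0)) {
    stop("link counts must be non-negative", call. = FALSE)
  }
  k <- k_C + k_S + k_D
  if (any(k == 0)) stop("node with zero links has no homogeneity", call. = FALSE)
  (k_C / k)^2 + (k_S / k)^2 + (k_D / k)^2
}

#' Per-node summaries of the typed network
#'
#' For every node: total and per-type degrees, homogeneity, the per-type
#' degree fractions (for ternary binning), the combination of types present
#' (the Venn partition cell), and a connectivity class (`leaf` k <= 2,
#' `intermediate` 3 <= k <= 10, `hub` k > 10).
#'
#' @param net An `igraph` typed network.
#' @return Data frame with columns `gene`, `k`, `k_C`, `k_S`, `k_D`, `H`,
#'   `frac_C`, `frac_S`, `frac_D`, `venn`, `class`.
#' @export
node_summaries <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network", call. = FALSE)
  genes <- igraph::V(net)$name
  ends <- igraph::as_edgelist(net)
  types <- igraph::E(net)$type
  kt <- sapply(c("C", "S", "D"), function(t) {
    e <- ends[types == t, , drop = FALSE]
    tab <- table(factor(c(e[, 1L], e[, 2L]), levels = genes))
    as.integer(tab)
  })
  if (is.null(dim(kt))) kt <- matrix(kt, nrow = 1L)  # single-node edge case
  k_C <- kt[, 1L]; k_S <- kt[, 2L]; k_D <- kt[, 3L]
  k <- k_C + k_S + k_D
  venn <- paste0(ifelse(k_C > 0, "C", ""), ifelse(k_S > 0, "S", ""),
                 ifelse(k_D > 0, "D", ""))
  out <- data.frame(gene = genes, k = k, k_C = k_C, k_S = k_S, k_D = k_D,
                    H = homogeneity(k_C, k_S, k_D),
                    frac_C = k_C / k, frac_S = k_S / k, frac_D = k_D / k,
                    venn = venn,
                    class = ifelse(k > 10, "hub",
                                   ifelse(k >= 3, "intermediate", "leaf")),
                    stringsAsFactors = FALSE)
  out[order(out$gene, method = "radix"), , drop = FALSE]
}

#' Connected components by size
#'
#' @param net An `igraph` network.
#' @return Data frame with one row per connected component: `nodes`,
#'   `edges`, sorted by node count (desc), then edge count (desc), then the
#'   lexicographically smallest member gene.
#' @export
component_decomposition <- function(net) {
  if (igraph::vcount(net) == 0L) {
    return(data.frame(nodes = integer(), edges = integer()))
  }
  comp <- igraph::components(net)
  genes <- igraph::V(net)$name
  ends <- igraph::as_edgelist(net, names = FALSE)
  edge_comp <- comp$membership[ends[, 1L]]
  n_edges <- tabulate(edge_comp, nbins = comp$no)
  smallest <- vapply(seq_len(comp$no), function(i) {
    min(genes[comp$membership == i])
  }, character(1L))
  out <- data.frame(nodes = as.integer(comp$csize),
                    edges = as.integer(n_edges),
                    stringsAsFactors = FALSE)
  ord <- order(-out$nodes, -out$edges, smallest, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hub tables per interaction type
#'
#' For each type t in C, S, D, ranks nodes by their t-type degree `k_t`
#' (ties broken by total degree desc, then gene id) and reports the top
#' `top_n` with their full degree breakdown and homogeneity. Nodes with
#' `k_t = 0` never appear in the t table. An overall table ranked by total
#' degree is included.
#'
#' @param net An `igraph` typed network.
#' @param top_n Number of rows per table (default 5).
#' @return Named list of data frames `C`, `S`, `D`, `overall`.
#' @export
hub_report <- function(net, top_n = 5) {
  if (top_n < 1) stop("top_n must be >= 1", call. = FALSE)
  ns <- node_summaries(net)
  pick <- function(key) {
    sub <- ns[ns[[key]] > 0, , drop = FALSE]
    ord <- order(-sub[[key]], -sub$k, sub$gene, method = "radix")
    head(sub[ord, c("gene", "k", "k_C", "k_S", "k_D", "H")], top_n)
  }
  overall <- ns[order(-ns$k, ns$gene, method = "radix"),
                c("gene", "k", "k_C", "k_S", "k_D", "H")]
  list(C = pick("k_C"), S = pick("k_S"), D = pick("k_D"),
       overall = head(overall, top_n))
}

#' Single-type subnetwork
#'
#' @param net An `igraph` typed network.
#' @param type One of "C", "S", "D".
#' @return The subgraph induced by edges of that type (isolated nodes
#'   dropped).
#' @export
type_subnetwork <- function(net, type = c("C", "S", "D")) {
  type <- match.arg(type)
  eids <- which(igraph::edge_attr(net, "type") == type)
  igraph::subgraph_from_edges(net, eids, delete.vertices = TRUE)
}
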