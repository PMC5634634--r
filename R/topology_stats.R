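#' Degree assortativity
#'
#' Newman's degree assortativity: the Pearson correlation of the excess
#' degrees (degree minus one) at the two ends of every edge, counting both
#' orientations. Positive values mean hubs preferentially attach to hubs.
#' On a regular graph the degrees at edge ends are constant and the
#' coefficient is undefined; `NA_real_` is returned as the marker.
#'
#' @param net An undirected `igraph` network with at least 2 edges.
#' @return Assortativity in \[-1, 1\], or `NA_real_` if degenerate.
#' @export
degree_assortativity <- function(net) {
  if (igraph::ecount(net) < 2L) {
    stop("need at least 2 edges for assortativity", call. = FALSE)
  }
  r <- suppressWarnings(igraph::assortativity_degree(net, directed = FALSE))
  if (!is.finite(r)) NA_real_ else r
}

#' Maximum k-core number
#'
#' The largest k for which the k-core (maximal subgraph of minimum degree
#' >= k) is non-empty, obtained by iterative peeling. Any tree has max
#' k-core 1; a clique of q nodes has q - 1.
#'
#' @param net A non-empty `igraph` network.
#' @return Integer >= 0 (0 only for edgeless graphs).
#' @export
max_kcore <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network", call. = FALSE)
  max(igraph::coreness(net))
}

#' Mean local clustering coefficient
#'
#' Average over all nodes of the proportion of a node's neighbour pairs
#' that are themselves connected; nodes with fewer than 2 neighbours
#' contribute 0.
#'
#' @param net A non-empty `igraph` network.
#' @return Value in \[0, 1\].
#' @export
mean_clustering <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network", call. = FALSE)
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  mean(cc)
}

#' Degree-preserving randomization by double edge swaps
#'
#' Repeatedly picks two edges and swaps their endpoints, rejecting swaps
#' that would create a self-loop or a parallel edge, so the degree of every
#' node is exactly preserved. Edge attributes are not meaningful after
#' rewiring and are dropped.
#'
#' @param net An `igraph` network with >= 2 edges.
#' @param swaps_per_edge Accepted swap attempts per edge (default 10).
#' @param seed Optional seed for reproducibility.
#' @return A rewired `igraph` network on the same vertex set.
#' @export
degree_preserving_rewire <- function(net, swaps_per_edge = 10, seed = NULL) {
  if (igraph::ecount(net) < 2L) stop("need at least 2 edges", call. = FALSE)
  niter <- as.integer(swaps_per_edge * igraph::ecount(net))
  g <- net
  # edge attributes are meaningless after rewiring; drop them
  for (attr in igraph::edge_attr_names(g)) {
    g <- igraph::delete_edge_attr(g, attr)
  }
  with_local_seed(seed, igraph::rewire(g, igraph::keeping_degseq(niter = niter)))
}

#' Compare a topology metric against degree-preserving null models
#'
#' Computes the empirical value of a metric and its distribution over
#' `n_random` independent degree-preserving rewirings, summarised as mean,
#' sd and the z-score `(empirical - null_mean)/null_sd`. With a rigid
#' degree sequence (e.g. a star) the null sd is 0 and the comparison is
#' flagged degenerate. The metric can be evaluated on the full network or
#' on a single-type subnetwork via `type`.
#'
#' @param net An `igraph` typed network.
#' @param metric One of "assortativity", "max_kcore", "clustering".
#' @param n_random Number of rewired networks (default 100).
#' @param seed Optional seed.
#' @param type Optional link type ("C", "S" or "D") to restrict to.
#' @param swaps_per_edge Passed to [degree_preserving_rewire()].
#' @return List of class `null_comparison`: `metric_name`, `empirical`,
#'   `null_mean`, `null_sd`, `z`, `n_random`, `seed`, `degenerate`.
#' @export
null_model_comparison <- function(net,
                                  metric = c("assortativity", "max_kcore", "clustering"),
                                  n_random = 100, seed = NULL, type = NULL,
                                  swaps_per_edge = 10) {
  metric <- match.arg(metric)
  if (!is.null(type)) net <- type_subnetwork(net, type)
  f <- switch(metric,
              assortativity = degree_assortativity,
              max_kcore = max_kcore,
              clustering = mean_clustering)
  empirical <- f(net)
  if (!is.finite(empirical)) {
    stop("metric '", metric, "' is degenerate on this network", call. = FALSE)
  }
  null_vals <- with_local_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      r <- degree_preserving_rewire(net, swaps_per_edge = swaps_per_edge)
      v <- f(r)
      if (!is.finite(v)) NA_real_ else v
    }, numeric(1L))
  })
  null_vals <- null_vals[is.finite(null_vals)]
  nm <- mean(null_vals)
  nsd <- stats::sd(null_vals)
  degenerate <- !is.finite(nsd) || nsd == 0
  structure(list(metric_name = metric, empirical = empirical,
                 null_mean = nm, null_sd = nsd,
                 z = if (degenerate) NA_real_ else (empirical - nm) / nsd,
                 n_random = n_random, seed = seed, degenerate = degenerate),
            class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf("%s: empirical %.4g vs null %.4g +/- %.4g over %d rewirings (%s)\n",
              x$metric_name, x$empirical, x$null_mean, x$null_sd, x$n_random,
              if (x$degenerate) "degenerate null" else sprintf("z = %.3g", x$z)))
  invisible(x)
}

edge_pair_keys <- function(a, b) {
  pr <- canonical_pair(a, b)
  paste(pr$a, pr$b, sep = "\r")
}

#' Edge overlap with a reference network, against a random-network null
#'
#' Counts the unordered gene pairs linked in both the query network and a
#' reference interaction network (e.g. a protein interaction network), and
#' compares that count to a null in which networks of the same size are
#' drawn at random from a gene universe: each null replicate samples
#' `|V|` genes from `node_pool` and then `|E|` distinct pairs uniformly
#' among those genes. The empirical p-value uses the add-one convention
#' `p = (1 + #\{null >= observed\}) / (n_random + 1)`.
#'
#' @param net_edges Two-column data frame (or a typed-pair table) of query
#'   edges.
#' @param reference_edges Two-column data frame of reference edges.
#' @param node_pool Character vector: the gene universe the query network
#'   was drawn from (must contain all query nodes).
#' @param n_random Number of null replicates (default 1000).
#' @param seed Optional seed.
#' @return List with `overlap`, `null_mean`, `null_sd`, `p`, `n_random`.
#' @export
edge_overlap_randomization <- function(net_edges, reference_edges, node_pool,
                                       n_random = 1000, seed = NULL) {
  a <- as.character(net_edges[[1L]]); b <- as.character(net_edges[[2L]])
  if ("gene_a" %in% names(net_edges)) {
    a <- net_edges$gene_a; b <- net_edges$gene_b
  }
  nodes <- unique(c(a, b))
  node_pool <- unique(as.character(node_pool))
  if (!all(nodes %in% node_pool)) {
    stop("node_pool must contain every node of the query network", call. = FALSE)
  }
  if (length(node_pool) < length(nodes)) {
    stop("node pool smaller than the query node set", call. = FALSE)
  }
  ref_keys <- unique(edge_pair_keys(as.character(reference_edges[[1L]]),
                                    as.character(reference_edges[[2L]])))
  qry_keys <- unique(edge_pair_keys(a, b))
  observed <- sum(qry_keys %in% ref_keys)
  n_nodes <- length(nodes)
  n_edges <- length(qry_keys)
  max_pairs <- choose(n_nodes, 2)
  if (n_edges > max_pairs) stop("more query edges than possible pairs", call. = FALSE)
  null_overlap <- with_local_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      vs <- sample(node_pool, n_nodes)
      # sample n_edges distinct unordered pairs among vs by index
      pair_idx <- sample.int(max_pairs, n_edges)
      # map linear index of upper triangle to (row, col), 1-based
      col <- ceiling((sqrt(8 * pair_idx + 1) - 1) / 2) + 1
      row <- pair_idx - (col - 1) * (col - 2) / 2
      sum(edge_pair_keys(vs[row], vs[col]) %in% ref_keys)
    }, numeric(1L))
  })
  list(overlap = observed,
       null_mean = mean(null_overlap),
       null_sd = stats::sd(null_overlap),
       p = (1 + sum(null_overlap >= observed)) / (n_random + 1),
       n_random = n_random)
}

#' Mean reference-network distance of a set of gene pairs
#'
#' For each query pair whose endpoints both lie in the reference network
#' and are connected there, computes the geodesic distance; pairs outside
#' the reference or in different components are dropped (with a logged
#' count). The mean distance is compared to a null built by sampling the
#' same number of finitely-distant vertex pairs uniformly from the
#' reference, repeated `n_samples` times.
#'
#' @param pairs Two-column data frame of gene pairs (or a typed-pair table).
#' @param reference An `igraph` reference network.
#' @param n_samples Null replicates (default 1000).
#' @param seed Optional seed.
#' @return List with `mean_distance`, `n_used`, `n_dropped`, `null_mean`,
#'   `null_sd`, `z`.
#' @export
mean_shortest_path_comparison <- function(pairs, reference, n_samples = 1000,
                                          seed = NULL) {
  a <- as.character(pairs[[1L]]); b <- as.character(pairs[[2L]])
  if ("gene_a" %in% names(pairs)) { a <- pairs$gene_a; b <- pairs$gene_b }
  ref_names <- igraph::V(reference)$name
  dm <- igraph::distances(reference)
  present <- a %in% ref_names & b %in% ref_names
  d <- rep(Inf, length(a))
  d[present] <- dm[cbind(a[present], b[present])]
  usable <- is.finite(d)
  n_dropped <- sum(!usable)
  if (n_dropped > 0L) {
    message("mean_shortest_path_comparison: dropped ", n_dropped,
            " pair(s) absent from or disconnected in the reference")
  }
  if (!any(usable)) stop("no usable pair", call. = FALSE)
  emp <- mean(d[usable])
  k <- sum(usable)
  pool <- dm[upper.tri(dm)]
  pool <- pool[is.finite(pool) & pool > 0]
  null_means <- with_local_seed(seed, {
    vapply(seq_len(n_samples),
           function(i) mean(pool[sample.int(length(pool), k,
                                            replace = k > length(pool))]),
           numeric(1L))
  })
  nm <- mean(null_means); nsd <- stats::sd(null_means)
  list(mean_distance = emp, n_used = k, n_dropped = n_dropped,
       null_mean = nm, null_sd = nsd,
       z = if (nsd > 0) (emp - nm) / nsd else NA_real_)
}

#' Rank reference-network genes by the short paths they mediate
#'
#' For every query pair connected in the reference by a shortest path of at
#' most `max_steps` edges, enumerates all shortest paths between the pair
#' and counts, for each non-endpoint gene, the number of such paths it lies
#' on. Directly linked pairs contribute no intermediary. The step limit
#' discards highly indirect connections unlikely to reflect a functional
#' relationship.
#'
#' @param pairs Two-column data frame of gene pairs.
#' @param reference An `igraph` reference network.
#' @param max_steps Maximum path length in edges (default 3).
#' @return Data frame `gene`, `n_paths`, sorted descending (ties by gene
#'   id); empty if no pair has an intermediary.
#' @export
intermediary_ranking <- function(pairs, reference, max_steps = 3) {
  a <- as.character(pairs[[1L]]); b <- as.character(pairs[[2L]])
  if ("gene_a" %in% names(pairs)) { a <- pairs$gene_a; b <- pairs$gene_b }
  ref_names <- igraph::V(reference)$name
  counts <- new.env(parent = emptyenv())
  for (i in seq_along(a)) {
    if (!(a[i] %in% ref_names) || !(b[i] %in% ref_names)) next
    d <- igraph::distances(reference, v = a[i], to = b[i])[1L, 1L]
    if (!is.finite(d) || d < 2 || d > max_steps) next
    sp <- igraph::all_shortest_paths(reference, from = a[i], to = b[i])$vpaths
    for (path in sp) {
      inner <- igraph::V(reference)$name[path][-c(1L, length(path))]
      for (g in inner) {
        counts[[g]] <- (if (is.null(counts[[g]])) 0L else counts[[g]]) + 1L
      }
    }
  }
  genes <- ls(counts)
  if (length(genes) == 0L) {
    return(data.frame(gene = character(), n_paths = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(gene = genes,
                    n_paths = vapply(genes, function(g) counts[[g]], integer(1L)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_paths, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set enrichment with Bonferroni correction
#'
#' For each gene set, tests whether the query gene list contains more of
#' the set's genes than expected from the background universe, using the
#' upper-tail hypergeometric probability `P(X >= overlap)` with population
#' = background, successes = set intersected with background, draws =
#' query size. Raw p-values are Bonferroni-corrected by the number of sets
#' tested (capped at 1).
#'
#' @param query Character vector of genes (must lie within `background`).
#' @param background Character vector: the gene universe.
#' @param collections Named list of character vectors (e.g. from
#'   [read_gmt()]); each set is intersected with the background first.
#' @return Data frame with one row per set: `set_name`, `overlap`,
#'   `set_size_in_background`, `query_size`, `background_size`, `fold`,
#'   `p_raw`, `p_corrected`; sorted by `p_raw`.
#' @export
hypergeometric_enrichment <- function(query, background, collections) {
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  query <- unique(as.character(query))
  if (!all(query %in% background)) {
    stop("query genes must be a subset of the background", call. = FALSE)
  }
  if (length(collections) == 0L) {
    stop("no gene sets supplied", call. = FALSE)
  }
  if (is.null(names(collections))) {
    stop("collections must be a named list", call. = FALSE)
  }
  N <- length(background)
  n <- length(query)
  n_sets <- length(collections)
  rows <- lapply(names(collections), function(nm) {
    set <- intersect(unique(as.character(collections[[nm]])), background)
    K <- length(set)
    ov <- length(intersect(query, set))
    p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    expected <- n * K / N
    data.frame(set_name = nm, overlap = ov, set_size_in_background = K,
               query_size = n, background_size = N,
               fold = if (expected > 0) ov / expected else NA_real_,
               p_raw = p, p_corrected = min(1, p * n_sets),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_raw, out$set_name, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene sets in GMT format
#'
#' Tab-delimited: set name, description, then member genes, one set per
#' line.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40), call. = FALSE)
    f[-c(1L, 2L)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L]
  }, character(1L), USE.NAMES = FALSE)
  sets
}

#' Read a two-column edge-list TSV as an igraph network
#'
#' @param path Path to a TSV with (at least) two columns of gene ids; a
#'   header is auto-detected.
#' @return An undirected simple `igraph` network.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  header <- grepl("gene|node|from|source", tolower(first))
  ed <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(ed) < 2L) stop("edge list needs two columns", call. = FALSE)
  g <- igraph::graph_from_data_frame(ed[, 1:2], directed = FALSE)
  igraph::simplify(g)
}
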