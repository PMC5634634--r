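# brute-force Newman assortativity: Pearson correlation of excess degrees
# over both orientations of every edge
assortativity_oracle <- function(g) {
  deg <- igraph::degree(g)
  e <- igraph::as_edgelist(g, names = FALSE)
  x <- c(deg[e[, 1]], deg[e[, 2]]) - 1
  y <- c(deg[e[, 2]], deg[e[, 1]]) - 1
  suppressWarnings(cor(x, y))
}

test_that("degree assortativity matches the excess-degree oracle", {
  star <- graph_from_pairs(rep("X", 4), paste0("L", 1:4))
  expect_equal(degree_assortativity(star), -1)
  cycle <- graph_from_pairs(c("A", "B", "C"), c("B", "C", "A"))
  expect_true(is.na(degree_assortativity(cycle)))  # regular graph: undefined
  path <- graph_from_pairs(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(degree_assortativity(path), assortativity_oracle(path))
})

test_that("assortativity agrees with the oracle on random graphs", {
  set.seed(2)
  for (i in 1:5) {
    g <- igraph::sample_gnp(30, 0.15)
    if (igraph::ecount(g) < 2) next
    expect_equal(degree_assortativity(g), assortativity_oracle(g),
                 tolerance = 1e-12)
  }
})

test_that("max k-core follows the peeling definition", {
  k4 <- graph_from_pairs(c("A", "A", "A", "B", "B", "C"),
                         c("B", "C", "D", "C", "D", "D"))
  expect_equal(max_kcore(k4), 3)
  tree <- graph_from_pairs(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(max_kcore(tree), 1)
  k4p <- igraph::add_edges(igraph::add_vertices(k4, 1, name = "E"),
                           c("A", "E"))
  expect_equal(max_kcore(k4p), 3)
})

test_that("mean local clustering averages with degree<2 contributing 0", {
  tri <- graph_from_pairs(c("A", "B", "C"), c("B", "C", "A"))
  expect_equal(mean_clustering(tri), 1)
  star <- graph_from_pairs(rep("X", 4), paste0("L", 1:4))
  expect_equal(mean_clustering(star), 0)
  trip <- igraph::add_edges(igraph::add_vertices(tri, 1, name = "P"),
                            c("A", "P"))
  expect_equal(mean_clustering(trip), 7 / 12)  # (1/3 + 1 + 1 + 0)/4
})

test_that("rewiring preserves the degree multiset exactly", {
  set.seed(12)
  g <- igraph::sample_pa(40, m = 2, directed = FALSE)
  for (i in 1:5) {
    r <- degree_preserving_rewire(g, swaps_per_edge = 10, seed = i)
    expect_equal(sort(igraph::degree(r)), sort(igraph::degree(g)))
    expect_false(igraph::any_multiple(r))
    expect_equal(sum(igraph::which_loop(r)), 0L)
  }
  # the triangle is the unique graph with its degree sequence
  tri <- graph_from_pairs(c("A", "B", "C"), c("B", "C", "A"))
  r <- degree_preserving_rewire(tri, seed = 1)
  expect_equal(unname(sort(igraph::degree(r))), c(2, 2, 2))
  expect_equal(igraph::ecount(r), 3L)
  two <- graph_from_pairs(c("A", "C"), c("B", "D"))
  r2 <- degree_preserving_rewire(two, seed = 1)
  expect_equal(igraph::ecount(r2), 2L)
  expect_true(all(igraph::degree(r2) == 1))
})

test_that("null model comparison is seeded and flags rigid degree sequences", {
  set.seed(8)
  g <- igraph::sample_gnp(30, 0.2)
  a <- null_model_comparison(g, "clustering", n_random = 10, seed = 42)
  b <- null_model_comparison(g, "clustering", n_random = 10, seed = 42)
  expect_equal(unclass(a), unclass(b))
  expect_equal(a$z, (a$empirical - a$null_mean) / a$null_sd)
  star <- graph_from_pairs(rep("X", 5), paste0("L", 1:5))
  s <- null_model_comparison(star, "max_kcore", n_random = 5, seed = 1)
  expect_true(s$degenerate)
  expect_true(is.na(s$z))
})

test_that("edge overlap: identity, disjoint and saturated-pool cases", {
  edges <- data.frame(a = c("A", "B", "C"), b = c("B", "C", "D"))
  pool <- c("A", "B", "C", "D", "E", "F")
  self <- edge_overlap_randomization(edges, edges, pool, n_random = 50, seed = 1)
  expect_equal(self$overlap, 3L)
  expect_true(self$p <= 1 && self$p > 0)

  ref2 <- data.frame(a = c("P", "Q"), b = c("Q", "R"))
  far <- edge_overlap_randomization(edges, ref2, pool, n_random = 50, seed = 1)
  expect_equal(far$overlap, 0L)
  expect_equal(far$p, 1)

  # reference = all 15 pairs of a 6-gene pool: every sampled pair overlaps
  allp <- t(combn(pool, 2))
  ref_all <- data.frame(a = allp[, 1], b = allp[, 2])
  sat <- edge_overlap_randomization(edges, ref_all, pool, n_random = 30, seed = 2)
  expect_equal(sat$null_mean, 3)
  expect_equal(sat$null_sd, 0)

  expect_error(edge_overlap_randomization(edges, ref2, c("A", "B")),
               "node_pool")
})

test_that("mean shortest-path comparison over a reference network", {
  path <- graph_from_pairs(c("A", "B", "C"), c("B", "C", "D"))
  direct <- data.frame(a = c("A", "B"), b = c("B", "C"))
  r <- mean_shortest_path_comparison(direct, path, n_samples = 20, seed = 1)
  expect_equal(r$mean_distance, 1)
  pairs <- data.frame(a = c("A", "A"), b = c("C", "D"))
  r2 <- mean_shortest_path_comparison(pairs, path, n_samples = 20, seed = 1)
  expect_equal(r2$mean_distance, 2.5)  # geodesics 2 and 3
  # disconnected pair dropped with a message
  two_comp <- graph_from_pairs(c("A", "X"), c("B", "Y"))
  expect_message(
    r3 <- mean_shortest_path_comparison(
      data.frame(a = c("A", "A"), b = c("B", "X")), two_comp,
      n_samples = 10, seed = 1),
    "dropped 1")
  expect_equal(r3$n_used, 1L)
  expect_error(suppressMessages(mean_shortest_path_comparison(
    data.frame(a = "A", b = "X"), two_comp)), "no usable pair")
})

test_that("intermediary ranking counts nodes on short shortest paths", {
  g <- graph_from_pairs(c("A", "X", "A", "Y", "A"),
                        c("X", "B", "Y", "B", "C"))
  r <- intermediary_ranking(data.frame(a = "A", b = "B"), g)
  expect_equal(r$n_paths[r$gene == "X"], 1L)
  expect_equal(r$n_paths[r$gene == "Y"], 1L)
  # directly linked pair contributes no intermediary
  r2 <- intermediary_ranking(data.frame(a = "A", b = "C"), g)
  expect_equal(nrow(r2), 0L)
  # beyond max_steps: contributes nothing
  chain <- graph_from_pairs(c("A", "B", "C", "D"), c("B", "C", "D", "E"))
  expect_equal(nrow(intermediary_ranking(data.frame(a = "A", b = "E"), chain)),
               0L)
  expect_equal(
    intermediary_ranking(data.frame(a = "A", b = "D"), chain)$gene,
    c("B", "C"))
})

test_that("hypergeometric enrichment matches the closed form", {
  bg <- paste0("g", 1:10)
  sets <- list(hit = paste0("g", 1:5))
  res <- hypergeometric_enrichment(paste0("g", 1:4), bg, sets)
  expect_equal(res$p_raw, choose(5, 4) * choose(5, 0) / choose(10, 4))
  expect_equal(res$overlap, 4L)
  expect_equal(res$fold, 4 / (4 * 5 / 10))
  # query = background: p = 1 for every set
  res2 <- hypergeometric_enrichment(bg, bg, sets)
  expect_equal(res2$p_raw, 1)
  # zero overlap: P(X >= 0) = 1
  res3 <- hypergeometric_enrichment(paste0("g", 6:8), bg,
                                    list(s = paste0("g", 1:3)))
  expect_equal(res3$p_raw, 1)
  # Bonferroni multiplies by the number of sets, capped at 1
  many <- list(a = paste0("g", 1:5), b = paste0("g", 2:6), c = paste0("g", 1:2))
  res4 <- hypergeometric_enrichment(paste0("g", 1:4), bg, many)
  expect_equal(res4$p_corrected, pmin(1, res4$p_raw * 3))
  expect_true(all(res4$p_raw <= res4$p_corrected))
  expect_error(hypergeometric_enrichment("x", character(), sets), "empty")
  expect_error(hypergeometric_enrichment("zz", bg, sets), "subset")
})

test_that("GMT and edge-list readers parse their formats", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), gmt)
  sets <- read_gmt(gmt)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setB, c("g4", "g5"))
  bad <- tempfile(); writeLines("just_one_field", bad)
  expect_error(read_gmt(bad), "malformed")

  el <- tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b", "A\tB", "B\tC", "A\tB"), el)
  g <- read_edge_list(el)
  expect_equal(igraph::ecount(g), 2L)  # duplicate collapsed
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
})
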