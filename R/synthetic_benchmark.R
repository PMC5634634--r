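#' Generate a random signed regulatory network
#'
#' Builds a directed regulator -> target network with a preferential
#' attachment flavour: endpoints are drawn with probability proportional to
#' current degree + 1, producing the broad degree distributions typical of
#' regulatory reconstructions. No self-regulation and at most one directed
#' edge per gene pair (reciprocal edges are never emitted, so each linked
#' pair has one unambiguous regulatory sign). Signs are +1/-1 with equal
#' probability; weight magnitudes are Uniform(0.5, 1.5), then globally
#' rescaled if needed so the weight matrix has spectral radius at most 0.8
#' and the linear expression model always has a stable fixed point.
#'
#' @param n_genes Number of genes.
#' @param n_edges Number of directed edges; at most `n_genes*(n_genes-1)/2`
#'   since reciprocal pairs are excluded.
#' @param seed Optional seed; the network is deterministic given the seed.
#' @return Object of class `signed_network`: list with `genes` (character)
#'   and `edges` (data frame `from`, `to`, `sign`, `weight`).
#' @export
generate_signed_network <- function(n_genes, n_edges, seed = NULL) {
  n_genes <- as.integer(n_genes)
  n_edges <- as.integer(n_edges)
  if (n_genes < 2L) stop("need at least 2 genes", call. = FALSE)
  max_edges <- n_genes * (n_genes - 1L) / 2
  if (n_edges < 1L || n_edges > max_edges) {
    stop(sprintf("n_edges must be in [1, %d] for %d genes (one directed edge per pair)",
                 max_edges, n_genes), call. = FALSE)
  }
  with_local_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    deg <- rep(0, n_genes)
    used <- new.env(parent = emptyenv())
    from <- integer(n_edges)
    to <- integer(n_edges)
    got <- 0L
    attempts <- 0L
    max_attempts <- 200L * n_edges
    while (got < n_edges && attempts < max_attempts) {
      attempts <- attempts + 1L
      reg <- sample.int(n_genes, 1L, prob = deg + 1)
      tgt <- sample.int(n_genes, 1L, prob = deg + 1)
      if (reg == tgt) next
      key <- paste(min(reg, tgt), max(reg, tgt))
      if (!is.null(used[[key]])) next
      used[[key]] <- TRUE
      got <- got + 1L
      from[got] <- reg
      to[got] <- tgt
      deg[reg] <- deg[reg] + 1
      deg[tgt] <- deg[tgt] + 1
    }
    if (got < n_edges) {
      # dense request: fill the remainder uniformly from the free pairs
      all_pairs <- utils::combn(n_genes, 2L)
      keys <- paste(all_pairs[1L, ], all_pairs[2L, ])
      free <- which(vapply(keys, function(k) is.null(used[[k]]), logical(1L)))
      pick <- sample(free, n_edges - got)
      for (idx in pick) {
        got <- got + 1L
        orient <- sample(c(TRUE, FALSE), 1L)
        from[got] <- if (orient) all_pairs[1L, idx] else all_pairs[2L, idx]
        to[got] <- if (orient) all_pairs[2L, idx] else all_pairs[1L, idx]
      }
    }
    sgn <- sample(c(-1, 1), n_edges, replace = TRUE)
    wt <- stats::runif(n_edges, 0.5, 1.5)
    W <- matrix(0, n_genes, n_genes)
    W[cbind(to, from)] <- sgn * wt
    radius <- max(Mod(eigen(W, only.values = TRUE)$values))
    if (radius > 0.8) wt <- wt * (0.8 / radius)
    structure(list(genes = genes,
                   edges = data.frame(from = genes[from], to = genes[to],
                                      sign = sgn, weight = wt,
                                      stringsAsFactors = FALSE)),
              class = "signed_network")
  })
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("signed regulatory network: %d genes, %d directed edges (%d +, %d -)\n",
              length(x$genes), nrow(x$edges),
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

#' Perturb a signed network and record ground-truth pair labels
#'
#' Removes a fraction of the edges and flips the sign of a disjoint
#' fraction, both chosen uniformly without replacement; counts are
#' `round(frac * |E|)` with halves rounded away from zero. Every directly
#' linked gene pair gets a ground-truth label for the benchmark: unchanged
#' edge -> C, removed -> S, sign-flipped -> D.
#'
#' @param net A `signed_network`.
#' @param frac_remove Fraction of edges to remove (default 0.05).
#' @param frac_flip Fraction of edges to sign-flip (default 0.05).
#' @param seed Optional seed.
#' @return List with `network` (the perturbed `signed_network`) and `truth`
#'   (data frame `gene_a`, `gene_b`, `label` with `gene_a < gene_b`).
#' @export
perturb_network <- function(net, frac_remove = 0.05, frac_flip = 0.05,
                            seed = NULL) {
  if (frac_remove < 0 || frac_flip < 0 || frac_remove + frac_flip > 1) {
    stop("need frac_remove, frac_flip >= 0 with sum <= 1", call. = FALSE)
  }
  E <- nrow(net$edges)
  n_rm <- as.integer(round_half_up(frac_remove * E))
  n_fl <- as.integer(round_half_up(frac_flip * E))
  if (n_rm + n_fl > E) stop("perturbation counts exceed edge count", call. = FALSE)
  with_local_seed(seed, {
    chosen <- if (n_rm + n_fl > 0L) sample.int(E, n_rm + n_fl) else integer()
    removed <- chosen[seq_len(n_rm)]
    flipped <- chosen[n_rm + seq_len(n_fl)]
    label <- rep("C", E)
    label[removed] <- "S"
    label[flipped] <- "D"
    edges2 <- net$edges
    edges2$sign[flipped] <- -edges2$sign[flipped]
    if (n_rm > 0L) edges2 <- edges2[-removed, , drop = FALSE]
    pr <- canonical_pair(net$edges$from, net$edges$to)
    truth <- data.frame(gene_a = pr$a, gene_b = pr$b, label = label,
                        stringsAsFactors = FALSE)
    list(network = structure(list(genes = net$genes, edges = edges2),
                             class = "signed_network"),
         truth = truth)
  })
}

signed_weight_matrix <- function(net) {
  G <- length(net$genes)
  W <- matrix(0, G, G, dimnames = list(net$genes, net$genes))
  W[cbind(match(net$edges$to, net$genes), match(net$edges$from, net$genes))] <-
    net$edges$sign * net$edges$weight
  W
}

#' Simulate expression data from a signed network
#'
#' Linear-Gaussian structural model: each sample draws independent standard
#' Gaussian exogenous inputs e and the expression vector is the fixed point
#' of x = Wx + e, i.e. x = (I - W)^-1 e, where W\[target, regulator\] is the
#' signed edge weight. Regulatory signs therefore propagate into the sign
#' structure of the pairwise correlations, which is all the rank-based
#' downstream analysis consumes. Independent Gaussian observation noise is
#' added on top.
#'
#' @param net A `signed_network` whose weight matrix has spectral
#'   radius < 1 (guaranteed by [generate_signed_network()]).
#' @param n_samples Number of samples (default 200).
#' @param noise_sd Observation noise sd; `NULL` (default) uses 0.1 times
#'   the sd of the noise-free signal.
#' @param seed Optional seed.
#' @param condition Condition label for the returned matrix.
#' @return An [expression_matrix()], genes x samples.
#' @export
simulate_expression <- function(net, n_samples = 200, noise_sd = NULL,
                                seed = NULL, condition = "synthetic") {
  W <- signed_weight_matrix(net)
  G <- nrow(W)
  radius <- max(Mod(eigen(W, only.values = TRUE)$values))
  if (radius >= 1) {
    stop(sprintf(paste0("weight matrix has spectral radius %.3f >= 1; the ",
                        "linear model x = Wx + e has no stable fixed point. ",
                        "Rescale the edge weights below 1."), radius),
         call. = FALSE)
  }
  with_local_seed(seed, {
    e <- matrix(stats::rnorm(G * n_samples), G, n_samples)
    x <- solve(diag(G) - W, e)
    if (is.null(noise_sd)) noise_sd <- 0.1 * stats::sd(as.vector(x))
    if (noise_sd > 0) x <- x + matrix(stats::rnorm(G * n_samples, sd = noise_sd),
                                      G, n_samples)
    expression_matrix(x, net$genes, sprintf("S%03d", seq_len(n_samples)),
                      condition)
  })
}

#' ROC curve and AUC for a score ranking
#'
#' Threshold-sweep ROC with tied scores grouped (one operating point per
#' distinct score value) and AUC by the trapezoid rule, which for a step
#' curve with grouped ties equals the normalised Mann-Whitney statistic
#' (ties counted 1/2).
#'
#' @param scores Numeric score per instance (higher = more positive).
#' @param positives Logical vector: which instances are positive.
#' @return List with `points` (data frame `fpr`, `tpr`, from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, positives) {
  if (length(scores) != length(positives)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  positives <- as.logical(positives)
  npos <- sum(positives)
  nneg <- sum(!positives)
  if (npos == 0L || nneg == 0L) {
    stop("need at least one positive and one negative", call. = FALSE)
  }
  r <- rank(scores)  # midranks: ties counted 1/2 in the AUC
  auc <- (sum(r[positives]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- positives[ord]
  last_of_group <- c(s[-1L] != s[-length(s)], TRUE)
  tpr <- cumsum(pos)[last_of_group] / npos
  fpr <- cumsum(!pos)[last_of_group] / nneg
  list(points = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)), auc = auc)
}

#' Run the synthetic perturbation benchmark
#'
#' One repeat: generate a signed regulatory network, perturb it (edge
#' removals -> S labels, sign flips -> D labels, the rest -> C), simulate
#' expression for the original and perturbed network, run the full scoring
#' stack (pair-unique subsampling, correlation profiles, C/S/D scores), and
#' evaluate each score as a ranking of the ground-truth labelled pairs by
#' ROC: for score t, pairs labelled t are positive and the other labelled
#' (directly linked) pairs negative. Results are averaged over repeats.
#'
#' The defaults are a desk-scale version of a regulatory-reconstruction
#' experiment: 200 genes, 480 edges, 10% perturbation split evenly between
#' removals and flips, 200 samples per condition, 5 repeats.
#'
#' @param n_genes,n_edges Network size (defaults 200, 480).
#' @param frac_remove,frac_flip Perturbed fractions (defaults 0.05, 0.05).
#' @param n_samples Samples per condition (default 200).
#' @param noise_sd Observation noise sd; `NULL` = 0.1 x signal sd.
#' @param n_repeats Number of independent repeats (default 5).
#' @param subsample_size Subsample size n; `NULL` = [default_subsample_size()].
#' @param seed Seed for the whole benchmark (deterministic given seed).
#' @param shuffle_labels If `TRUE`, permute ground-truth labels within each
#'   repeat before scoring ROC — a null control whose AUCs should be 0.5.
#' @param keep_scores If `TRUE`, attach each repeat's full score table with
#'   a `label` column (`NA` for unlabelled pairs), for downstream
#'   structural checks such as thresholding the benchmark scores.
#' @return Object of class `csd_benchmark`: list with `auc` (data frame,
#'   one row per repeat, columns `C`, `S`, `D`), `mean_auc`, `roc` (per
#'   type, mean TPR on a common FPR grid), `config`, and optionally
#'   `scores`.
#' @export
run_benchmark <- function(n_genes = 200, n_edges = 480,
                          frac_remove = 0.05, frac_flip = 0.05,
                          n_samples = 200, noise_sd = NULL,
                          n_repeats = 5, subsample_size = NULL,
                          seed = NULL, shuffle_labels = FALSE,
                          keep_scores = FALSE) {
  if (is.null(subsample_size)) subsample_size <- default_subsample_size(n_samples)
  if (is.na(subsample_size)) {
    stop("too few samples to subsample; give subsample_size explicitly",
         call. = FALSE)
  }
  design <- generate_subsample_design(n_samples, subsample_size)
  grid <- seq(0, 1, by = 0.01)
  types <- c("C", "S", "D")
  with_local_seed(seed, {
    auc <- matrix(NA_real_, n_repeats, 3L, dimnames = list(NULL, types))
    tprs <- lapply(types, function(t) matrix(NA_real_, n_repeats, length(grid)))
    names(tprs) <- types
    score_tables <- if (keep_scores) vector("list", n_repeats) else NULL
    for (r in seq_len(n_repeats)) {
      net1 <- generate_signed_network(n_genes, n_edges)
      pert <- perturb_network(net1, frac_remove, frac_flip)
      m1 <- simulate_expression(net1, n_samples, noise_sd, condition = "cond1")
      m2 <- simulate_expression(pert$network, n_samples, noise_sd,
                                condition = "cond2")
      pc1 <- pair_correlation_profile(m1, design)
      pc2 <- pair_correlation_profile(m2, design)
      st <- csd_score_table(pc1, pc2)
      key_st <- paste(st$gene_a, st$gene_b)
      key_tr <- paste(pert$truth$gene_a, pert$truth$gene_b)
      idx <- match(key_tr, key_st)
      labelled <- st[idx[!is.na(idx)], , drop = FALSE]
      labels <- pert$truth$label[!is.na(idx)]
      if (shuffle_labels) labels <- sample(labels)
      for (t in types) {
        rc <- roc_curve(labelled[[t]], labels == t)
        auc[r, t] <- rc$auc
        tprs[[t]][r, ] <- stats::approx(rc$points$fpr, rc$points$tpr,
                                        xout = grid, ties = max,
                                        yleft = 0, yright = 1)$y
      }
      if (keep_scores) {
        st$label <- NA_character_
        st$label[idx[!is.na(idx)]] <- labels
        score_tables[[r]] <- st
      }
    }
    roc <- lapply(types, function(t) {
      data.frame(fpr = grid, tpr = colMeans(tprs[[t]]))
    })
    names(roc) <- types
    structure(list(auc = as.data.frame(auc),
                   mean_auc = colMeans(auc),
                   roc = roc,
                   config = list(n_genes = n_genes, n_edges = n_edges,
                                 frac_remove = frac_remove,
                                 frac_flip = frac_flip,
                                 n_samples = n_samples, noise_sd = noise_sd,
                                 n_repeats = n_repeats,
                                 subsample_size = subsample_size,
                                 seed = seed,
                                 shuffle_labels = shuffle_labels),
                   scores = score_tables),
              class = "csd_benchmark")
  })
}

#' @export
print.csd_benchmark <- function(x, ...) {
  cat(sprintf(
    "CSD benchmark: %d genes, %d edges, %d samples/condition, %d repeat(s)%s\n",
    x$config$n_genes, x$config$n_edges, x$config$n_samples,
    x$config$n_repeats,
    if (isTRUE(x$config$shuffle_labels)) " [label-shuffled control]" else ""))
  cat(sprintf("mean AUC: C = %.3f, S = %.3f, D = %.3f\n",
              x$mean_auc[["C"]], x$mean_auc[["S"]], x$mean_auc[["D"]]))
  invisible(x)
}
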