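#' Conserved, specific and differentiated co-expression scores
#'
#' For a gene pair with Spearman correlations `rho1`, `rho2` in the two
#' conditions and subsampling standard errors `sigma1`, `sigma2`, the three
#' scores are
#' \deqn{C = |\rho_1 + \rho_2| / d,\quad
#'       S = ||\rho_1| - |\rho_2|| / d,\quad
#'       D = (|\rho_1| + |\rho_2| - |\rho_1 + \rho_2|) / d,}
#' with \eqn{d = \sqrt{\sigma_1^2 + \sigma_2^2}}. C is large for strong
#' same-sign correlation in both conditions, S for strong correlation in
#' exactly one condition, D for strong correlation with opposite signs.
#' Two identities follow algebraically and are useful checks:
#' `C + D = (|rho1| + |rho2|)/d`, and `D = 0` exactly when
#' `rho1 * rho2 >= 0`.
#'
#' When `d = 0` for a pair (both sigmas zero, e.g. neither condition could
#' be subsampled and the fallback was 0), the denominator is replaced by 1,
#' which reduces the scores to their numerators.
#'
#' All arguments are vectorised over pairs.
#'
#' @param rho1,rho2 Correlations in \[-1, 1\].
#' @param sigma1,sigma2 Non-negative standard errors.
#' @return A data frame with columns `C`, `S`, `D` and the denominator
#'   `denom` actually used.
#' @export
csd_scores <- function(rho1, rho2, sigma1, sigma2) {
  args <- list(rho1, rho2, sigma1, sigma2)
  len <- vapply(args, length, integer(1L))
  if (length(unique(len)) != 1L) stop("inputs differ in length", call. = FALSE)
  if (!all(vapply(args, function(a) all(is.finite(a)), logical(1L)))) {
    stop("non-finite input", call. = FALSE)
  }
  if (any(abs(rho1) > 1 + 1e-12) || any(abs(rho2) > 1 + 1e-12)) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  if (any(sigma1 < 0) || any(sigma2 < 0)) {
    stop("standard errors must be non-negative", call. = FALSE)
  }
  d <- sqrt(sigma1^2 + sigma2^2)
  d[d == 0] <- 1
  data.frame(C = abs(rho1 + rho2) / d,
             S = abs(abs(rho1) - abs(rho2)) / d,
             D = (abs(rho1) + abs(rho2) - abs(rho1 + rho2)) / d,
             denom = d)
}

#' Score every gene pair across two conditions
#'
#' Joins two [pair_correlation_profile()] results on their (shared, aligned)
#' gene set and computes C/S/D scores for every unordered gene pair. Pairs
#' with an undefined correlation in either condition (a constant gene) are
#' excluded. When both conditions were subsampled their subsample sizes must
#' agree, otherwise the two sigmas would be on different scales and one
#' condition would dominate the score denominator.
#'
#' @param pc1,pc2 `pair_correlations` for condition 1 and 2.
#' @return A data frame with one row per scored pair: `gene_a`, `gene_b`
#'   (a < b), `rho1`, `sigma1`, `rho2`, `sigma2`, `C`, `S`, `D`, `denom`.
#'   The number of undefined pairs dropped is attached as attribute
#'   `n_dropped_undefined`.
#' @export
csd_score_table <- function(pc1, pc2) {
  if (!inherits(pc1, "pair_correlations") || !inherits(pc2, "pair_correlations")) {
    stop("inputs must be pair_correlations objects", call. = FALSE)
  }
  if (!identical(pc1$gene_ids, pc2$gene_ids)) {
    stop("the two profiles are not on the same aligned gene set", call. = FALSE)
  }
  if (pc1$subsampling_used && pc2$subsampling_used &&
      pc1$subsample_size != pc2$subsample_size) {
    stop("subsample size differs between conditions (", pc1$subsample_size,
         " vs ", pc2$subsample_size, "); the same n must be used for both",
         call. = FALSE)
  }
  genes <- pc1$gene_ids
  G <- length(genes)
  ut <- upper.tri(pc1$rho)
  ia <- row(pc1$rho)[ut]
  ib <- col(pc1$rho)[ut]
  rho1 <- pc1$rho[ut]; sigma1 <- pc1$sigma[ut]
  rho2 <- pc2$rho[ut]; sigma2 <- pc2$sigma[ut]
  ok <- is.finite(rho1) & is.finite(rho2)
  n_dropped <- sum(!ok)
  ia <- ia[ok]; ib <- ib[ok]
  rho1 <- rho1[ok]; sigma1 <- sigma1[ok]
  rho2 <- rho2[ok]; sigma2 <- sigma2[ok]
  pr <- canonical_pair(genes[ia], genes[ib])
  sc <- csd_scores(rho1, rho2, sigma1, sigma2)
  out <- data.frame(gene_a = pr$a, gene_b = pr$b,
                    rho1 = rho1, sigma1 = sigma1,
                    rho2 = rho2, sigma2 = sigma2,
                    C = sc$C, S = sc$S, D = sc$D, denom = sc$denom,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped_undefined") <- n_dropped
  out
}

#' Sampled-maxima score threshold
#'
#' The cutoff at importance level `p = 1/L` for a score distribution of `M`
#' values is the average, over `m` independent draws of `L` values each
#' (without replacement within a draw), of the per-draw maximum:
#' \deqn{X_p = \frac{1}{m} \sum_{i=1}^{m} \max\{s_i\}.}
#' This maps score distributions with very different shapes onto a common
#' importance scale; it is a ranking device, not a significance test.
#'
#' @param scores Numeric vector of scores (length M).
#' @param L Draw size, `1 <= L <= M`.
#' @param m Number of draws (default 100).
#' @param seed Optional seed for reproducible draws.
#' @return The cutoff value.
#' @export
sample_max_threshold <- function(scores, L, m = 100, seed = NULL) {
  M <- length(scores)
  if (M == 0L) stop("empty score list", call. = FALSE)
  if (L < 1L) stop("L must be >= 1", call. = FALSE)
  if (L > M) stop("draw size L exceeds the number of scores", call. = FALSE)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  with_local_seed(seed, {
    mean(vapply(seq_len(m),
                function(i) max(scores[sample.int(M, L)]),
                numeric(1L)))
  })
}

#' Cutoffs for C, S and D at a common importance level
#'
#' Applies [sample_max_threshold()] to each of the three score distributions
#' with the same `(L, m)`, giving cutoffs that correspond to the same
#' importance level `p = 1/L` despite the three distributions' very
#' different shapes. Summary statistics of the three distributions are
#' logged via `message()`.
#'
#' @param scores A score table from [csd_score_table()].
#' @param L Draw size; the network importance level is `p = 1/L`
#'   (default 1e5, i.e. p = 1e-5).
#' @param m Number of draws (default 100).
#' @param seed Optional seed.
#' @return An object of class `csd_thresholds`: list with `X_C`, `X_S`,
#'   `X_D`, `p`, `L`, `m`, `seed`.
#' @export
determine_thresholds <- function(scores, L = 1e5, m = 100, seed = NULL) {
  for (col in c("C", "S", "D")) {
    q <- stats::quantile(scores[[col]], c(0, .5, 1))
    message(sprintf(
      "%s-score distribution: M = %d, min %.4g, median %.4g, max %.4g, mean %.4g, sd %.4g",
      col, length(scores[[col]]), q[1L], q[2L], q[3L],
      mean(scores[[col]]), stats::sd(scores[[col]])))
  }
  with_local_seed(seed, {
    th <- list(X_C = sample_max_threshold(scores$C, L, m),
               X_S = sample_max_threshold(scores$S, L, m),
               X_D = sample_max_threshold(scores$D, L, m),
               p = 1 / L, L = L, m = m, seed = seed)
    structure(th, class = "csd_thresholds")
  })
}

#' @export
print.csd_thresholds <- function(x, ...) {
  cat(sprintf(
    "CSD cutoffs at importance level p = %g (L = %g, m = %d):\n  X_C = %.4g, X_S = %.4g, X_D = %.4g\n",
    x$p, x$L, x$m, x$X_C, x$X_S, x$X_D))
  invisible(x)
}

#' Classify gene pairs into typed links
#'
#' Keeps every pair whose C, S or D score exceeds its cutoff and assigns it
#' a single type. At high cutoffs the three score regions are mutually
#' exclusive; below that regime a pair may exceed more than one cutoff, in
#' which case the type with the largest score/cutoff ratio wins (ties broken
#' in the order C, S, D). The number of such multi-category hits is logged.
#'
#' @param scores A score table from [csd_score_table()].
#' @param th A `csd_thresholds` object (or a list with `X_C`, `X_S`, `X_D`).
#' @return A data frame of typed pairs: `gene_a`, `gene_b`, `type`, `score`,
#'   `rho1`, `rho2`.
#' @export
classify_pairs <- function(scores, th) {
  cuts <- c(C = th$X_C, S = th$X_S, D = th$X_D)
  if (any(!is.finite(cuts)) || any(cuts <= 0)) {
    stop("cutoffs must be finite and positive", call. = FALSE)
  }
  ratio <- cbind(C = scores$C / cuts[["C"]],
                 S = scores$S / cuts[["S"]],
                 D = scores$D / cuts[["D"]])
  n_hit <- rowSums(ratio > 1)
  keep <- n_hit > 0L
  n_multi <- sum(n_hit > 1L)
  if (n_multi > 0L) {
    message("classify_pairs: ", n_multi,
            " pair(s) exceeded more than one cutoff; assigned by largest score/cutoff ratio")
  }
  if (!any(keep)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      type = character(), score = numeric(),
                      rho1 = numeric(), rho2 = numeric(),
                      stringsAsFactors = FALSE))
  }
  rk <- ratio[keep, , drop = FALSE]
  type <- c("C", "S", "D")[max.col(rk, ties.method = "first")]
  sk <- scores[keep, , drop = FALSE]
  score <- vapply(seq_along(type),
                  function(i) sk[[type[i]]][i], numeric(1L))
  data.frame(gene_a = sk$gene_a, gene_b = sk$gene_b, type = type,
             score = score, rho1 = sk$rho1, rho2 = sk$rho2,
             stringsAsFactors = FALSE)
}
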