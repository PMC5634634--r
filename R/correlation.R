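#' Rank-transform a numeric vector
#'
#' Ranks 1..length with average ranks on ties, the transform underlying the
#' Spearman correlation. The rank sum is always `len(len+1)/2`.
#'
#' @param x Numeric vector of length >= 2 with finite entries.
#' @return Numeric vector of ranks.
#' @export
rank_transform <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values to rank", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite value in input", call. = FALSE)
  rank(x, ties.method = "average")
}

#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of the rank-transformed vectors. Returns `NA_real_`
#' (the undefined marker) when either vector is constant, since the rank
#' variance is then zero.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in \[-1, 1\], or `NA_real_` if undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  rx <- rank_transform(x)
  ry <- rank_transform(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Default subsample size for N samples
#'
#' The subsample count is maximised when `n^2 = N`, while rank correlations
#' on fewer than 7 points are too coarse for three-digit accuracy, so the
#' default is `floor(sqrt(N))` clipped below at 7.
#'
#' @param N Number of samples.
#' @return Integer subsample size, or `NA` if `N` is too small to subsample
#'   at that size.
#' @export
default_subsample_size <- function(N) {
  n <- max(7L, as.integer(floor(sqrt(N))))
  if (n > N) return(NA_integer_)
  n
}

#' Generate the pair-unique subsample design
#'
#' Deterministically partitions sample indices `1..N` into as many size-`n`
#' subsets as possible such that no pair of indices ever co-occurs in more
#' than one subset. The construction is:
#'
#' 1. Order the points `1..N`.
#' 2. First pass: consecutive disjoint blocks of size `n`
#'    (`floor(N/n)` blocks; remainder points are left for later passes).
#' 3. For each initiating point `n* = 1, 2, ..., N` in turn, sweep the points
#'    in order, adding to the current subset any point that has never
#'    co-occurred with a current member; emit the subset when it reaches
#'    size `n` and re-initiate from the same `n*`.
#' 4. When no full subset can be formed for `n*`, advance to the next
#'    initiating point; stop after `n* = N`. Incomplete subsets are dropped.
#'
#' Per-pair Spearman correlations over these subsets are independent in the
#' sense that no two subsets share a pair of samples, which is what makes
#' their standard error a usable intra-condition variability estimate.
#'
#' @param N Total sample count.
#' @param n Subsample size, `2 <= n <= N`.
#' @return An object of class `subsample_design`: a list with `N`, `n` and
#'   `subsamples` (list of integer index vectors, each of length `n`).
#' @export
generate_subsample_design <- function(N, n) {
  N <- as.integer(N)
  n <- as.integer(n)
  if (is.na(N) || is.na(n) || n < 2L || n > N) {
    stop("need 2 <= n <= N", call. = FALSE)
  }
  if (N < 49L) {
    warning("N = ", N, " samples is below the recommended minimum of 49 ",
            "for stable correlation standard errors", call. = FALSE)
  }
  cooc <- matrix(FALSE, N, N)
  subsamples <- list()
  emit <- function(idx) {
    subsamples[[length(subsamples) + 1L]] <<- idx
    cooc[idx, idx] <<- TRUE
  }
  for (b in seq_len(N %/% n)) {
    emit(seq.int((b - 1L) * n + 1L, b * n))
  }
  for (nstar in seq_len(N)) {
    repeat {
      current <- nstar
      for (p in seq_len(N)) {
        if (p == nstar) next
        if (any(cooc[p, current])) next
        current <- c(current, p)
        if (length(current) == n) break
      }
      if (length(current) < n) break
      emit(current)
    }
  }
  structure(list(N = N, n = n, subsamples = subsamples),
            class = "subsample_design")
}

#' @export
print.subsample_design <- function(x, ...) {
  cat(sprintf("subsample design: N = %d, n = %d, %d pair-unique subsamples\n",
              x$N, x$n, length(x$subsamples)))
  invisible(x)
}

#' Pairwise Spearman correlations with subsampling standard errors
#'
#' For one condition, computes the full-sample Spearman correlation for every
#' gene pair and, if a subsample design is supplied, the standard error of
#' the mean of the per-subsample correlations: the sample standard deviation
#' (denominator m - 1) of the m subsample correlations divided by sqrt(m).
#' A subsample correlation that is undefined (a gene constant within that
#' subsample) is dropped and m reduced for that pair; if fewer than 2 valid
#' values remain the pair's sigma falls back to `sigma_fallback`.
#'
#' Without a design (too few samples to subsample), all sigmas are set to
#' `sigma_fallback`: 0 when the other condition is subsampled, 1 when
#' neither condition can be (the score denominator then degenerates to a
#' constant; see [csd_scores()]).
#'
#' Genes constant across the full sample have undefined correlations; their
#' pairs are marked `NA` and excluded from scoring downstream.
#'
#' @param m An [expression_matrix()].
#' @param design A [generate_subsample_design()] object, or `NULL` to skip
#'   subsampling.
#' @param sigma_fallback Non-negative constant used where no subsampling
#'   estimate exists (default 0).
#' @return An object of class `pair_correlations`: list with `condition`,
#'   `gene_ids`, symmetric matrices `rho` and `sigma`, `n_subsamples`,
#'   `subsample_size`, and `subsampling_used`.
#' @export
pair_correlation_profile <- function(m, design = NULL, sigma_fallback = 0) {
  if (sigma_fallback < 0) stop("sigma_fallback must be >= 0", call. = FALSE)
  vals <- unclass(m)
  genes <- rownames(vals)
  G <- nrow(vals)
  rho <- suppressWarnings(stats::cor(t(vals), method = "spearman"))
  diag(rho) <- NA_real_
  if (is.null(design)) {
    sigma <- matrix(sigma_fallback, G, G, dimnames = dimnames(rho))
    diag(sigma) <- NA_real_
    sigma[is.na(rho)] <- NA_real_
    return(structure(list(condition = condition_label(m), gene_ids = genes,
                          rho = rho, sigma = sigma, n_subsamples = 0L,
                          subsample_size = NA_integer_,
                          subsampling_used = FALSE),
                     class = "pair_correlations"))
  }
  if (!inherits(design, "subsample_design")) {
    stop("design must be a subsample_design", call. = FALSE)
  }
  if (design$N != ncol(vals)) {
    stop(sprintf("design is for N = %d samples but the matrix has %d",
                 design$N, ncol(vals)), call. = FALSE)
  }
  n_sub <- length(design$subsamples)
  if (n_sub < 2L) {
    stop("design yields fewer than 2 subsamples; standard error undefined",
         call. = FALSE)
  }
  cnt <- matrix(0, G, G)
  s1 <- matrix(0, G, G)
  s2 <- matrix(0, G, G)
  for (idx in design$subsamples) {
    r <- suppressWarnings(stats::cor(t(vals[, idx, drop = FALSE]),
                                     method = "spearman"))
    ok <- is.finite(r)
    r[!ok] <- 0
    cnt <- cnt + ok
    s1 <- s1 + r
    s2 <- s2 + r * r
  }
  sigma <- matrix(sigma_fallback, G, G)
  enough <- cnt >= 2
  v <- (s2[enough] - s1[enough]^2 / cnt[enough]) / (cnt[enough] - 1)
  sigma[enough] <- sqrt(pmax(v, 0) / cnt[enough])
  dimnames(sigma) <- dimnames(rho)
  diag(sigma) <- NA_real_
  sigma[is.na(rho)] <- NA_real_
  structure(list(condition = condition_label(m), gene_ids = genes,
                 rho = rho, sigma = sigma, n_subsamples = n_sub,
                 subsample_size = design$n, subsampling_used = TRUE),
            class = "pair_correlations")
}

#' @export
print.pair_correlations <- function(x, ...) {
  cat(sprintf(
    "pair correlations for '%s': %d genes, %s\n",
    x$condition, length(x$gene_ids),
    if (x$subsampling_used) {
      sprintf("%d subsamples of size %d", x$n_subsamples, x$subsample_size)
    } else "no subsampling (fallback sigma)"))
  invisible(x)
}

#' Expected number of spuriously perfect rank correlations
#'
#' For two genuinely uncorrelated genes measured on N samples (no ties), the
#' probability that the Spearman correlation comes out exactly 1 is 1/N!, so
#' a study of G genes carries an expected `choose(G, 2) / N!` perfectly
#' correlated pairs by pure chance. With small N this swamps any threshold
#' on the correlation itself, which is why a minimum sample size matters.
#'
#' @param n_genes Number of genes G.
#' @param n_samples Number of samples N per gene.
#' @return Expected count of spurious perfect correlations.
#' @export
expected_spurious_perfect <- function(n_genes, n_samples) {
  choose(n_genes, 2) / factorial(n_samples)
}
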