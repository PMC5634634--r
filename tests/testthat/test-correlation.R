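test_that("rank transform averages ties and validates input", {
  expect_equal(rank_transform(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(rank_transform(c(1, 1, 2)), c(1.5, 1.5, 3))
  expect_equal(rank_transform(c(5, 5, 5)), c(2, 2, 2))
  expect_equal(sum(rank_transform(rnorm(11))), 11 * 12 / 2)
  expect_error(rank_transform(c(1, NA)), "non-finite")
  expect_error(rank_transform(3), "at least 2")
})

test_that("spearman_rho matches hand-derived values and flags constants", {
  x <- 1:7
  expect_equal(spearman_rho(x, exp(x)), 1)
  expect_equal(spearman_rho(x, -x^3), -1)
  # deviations of ranks (-1.5,-0.5,0.5,1.5)x(-1.5,0.5,-0.5,1.5) => 0.8
  expect_equal(spearman_rho(1:4, c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(spearman_rho(c(2, 2, 2), 1:3)))
  expect_error(spearman_rho(1:3, 1:4), "length")
})

test_that("spearman is invariant under strictly increasing transforms", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(30)
    y <- rnorm(30)
    expect_equal(spearman_rho(exp(x), y^3 + 5 * y), spearman_rho(x, y))
  }
})

test_that("subsample design reproduces the worked first-pass blocks", {
  d <- generate_subsample_design(100, 8)
  first <- lapply(1:12, function(b) seq((b - 1) * 8 + 1, b * 8))
  expect_equal(d$subsamples[1:12], first)
  expect_equal(max_pair_cooccurrence(d), 1L)
})

test_that("N=4, n=2 exhausts every pair exactly once", {
  d <- suppressWarnings(generate_subsample_design(4, 2))
  got <- lapply(d$subsamples, sort)
  expect_setequal(
    vapply(got, paste, collapse = ",", character(1)),
    c("1,2", "3,4", "1,3", "1,4", "2,3", "2,4"))
})

test_that("greedy passes emit only full, pair-unique subsamples", {
  d <- suppressWarnings(generate_subsample_design(9, 3))
  expect_true(all(lengths(d$subsamples) == 3L))
  expect_equal(max_pair_cooccurrence(d), 1L)
  expect_error(generate_subsample_design(5, 6), "n <= N")
  expect_error(generate_subsample_design(5, 1), "2 <= n")
  expect_warning(generate_subsample_design(20, 4), "49")
})

test_that("pair-uniqueness holds across random (N, n) configurations", {
  set.seed(202)
  for (i in 1:12) {
    N <- sample(10:200, 1)
    n <- sample(2:min(N, 20), 1)
    d <- suppressWarnings(generate_subsample_design(N, n))
    expect_equal(max_pair_cooccurrence(d), 1L,
                 label = sprintf("max co-occurrence for N=%d n=%d", N, n))
    expect_true(all(lengths(d$subsamples) == n))
    # deterministic given (N, n)
    d2 <- suppressWarnings(generate_subsample_design(N, n))
    expect_identical(d$subsamples, d2$subsamples)
  }
})

test_that("default subsample size is floor(sqrt(N)) clipped at 7", {
  expect_equal(default_subsample_size(100), 10L)
  expect_equal(default_subsample_size(49), 7L)
  expect_equal(default_subsample_size(30), 7L)  # clipped up
  expect_true(is.na(default_subsample_size(5)))
})

test_that("perfectly monotone pairs give rho 1 and sigma 0", {
  x <- rnorm(64)
  m <- make_expr(rbind(x, 2 * x + 3, rnorm(64)))
  d <- generate_subsample_design(64, 8)
  pc <- pair_correlation_profile(m, d)
  expect_equal(pc$rho["G1", "G2"], 1)
  expect_equal(pc$sigma["G1", "G2"], 0)
  expect_true(pc$subsampling_used)
})

test_that("sigma matches an independent SEM oracle over the subsamples", {
  set.seed(33)
  m <- make_expr(matrix(rnorm(6 * 25), 6, 25))
  d <- suppressWarnings(generate_subsample_design(25, 5))
  pc <- pair_correlation_profile(m, d)
  vals <- unclass(m)
  for (i in 1:5) for (j in (i + 1):6) {
    rs <- vapply(d$subsamples, function(s) {
      suppressWarnings(cor(vals[i, s], vals[j, s], method = "spearman"))
    }, numeric(1))
    rs <- rs[is.finite(rs)]
    expect_equal(pc$sigma[i, j], sd(rs) / sqrt(length(rs)),
                 tolerance = 1e-12)
    expect_equal(pc$rho[i, j],
                 cor(vals[i, ], vals[j, ], method = "spearman"))
  }
  expect_equal(pc$rho, t(pc$rho))
  expect_equal(pc$sigma, t(pc$sigma))
})

test_that("two subsample correlations of 0.5 and 0.7 give sigma 0.1", {
  # rank permutations with sum(d^2) = 10 and 6 give Spearman exactly
  # 0.5 and 0.7 on 5 points (rho = 1 - sum(d^2)/20); the SEM is then
  # sd(c(0.5, 0.7))/sqrt(2) = 0.1414.../1.4142... = 0.1
  d <- structure(list(N = 10L, n = 5L, subsamples = list(1:5, 6:10)),
                 class = "subsample_design")
  g1 <- 1:10
  g2 <- c(2, 4, 1, 3, 5, 5 + c(1, 2, 4, 5, 3))
  m <- make_expr(rbind(g1, g2))
  expect_equal(cor(g1[1:5], g2[1:5], method = "spearman"), 0.5)
  expect_equal(cor(g1[6:10], g2[6:10], method = "spearman"), 0.7)
  pc <- pair_correlation_profile(m, d)
  expect_equal(pc$sigma[1, 2], 0.1)
})

test_that("without a design all sigmas equal the declared fallback", {
  m <- make_expr(matrix(rnorm(30), 3, 10))
  pc0 <- pair_correlation_profile(m, NULL, sigma_fallback = 0)
  expect_true(all(pc0$sigma[upper.tri(pc0$sigma)] == 0))
  expect_false(pc0$subsampling_used)
  pc1 <- pair_correlation_profile(m, NULL, sigma_fallback = 1)
  expect_true(all(pc1$sigma[upper.tri(pc1$sigma)] == 1))
})

test_that("constant genes are flagged undefined, and tiny designs error", {
  m <- make_expr(rbind(rep(1, 10), rnorm(10), rnorm(10)))
  pc <- pair_correlation_profile(m, NULL, 0)
  expect_true(is.na(pc$rho["G1", "G2"]))
  expect_true(is.na(pc$sigma["G1", "G2"]))
  expect_false(is.na(pc$rho["G2", "G3"]))
  d1 <- structure(list(N = 10L, n = 10L, subsamples = list(1:10)),
                  class = "subsample_design")
  expect_error(pair_correlation_profile(m, d1), "fewer than 2 subsamples")
  d2 <- suppressWarnings(generate_subsample_design(9, 3))
  expect_error(pair_correlation_profile(m, d2), "N = 9")
})

test_that("larger subsamples track the full-sample correlation more closely", {
  # bivariate data with a fixed latent correlation: the mean subsample
  # correlation approaches the full-sample value as n grows
  set.seed(55)
  N <- 144
  x <- rnorm(N)
  y <- 0.7 * x + sqrt(1 - 0.49) * rnorm(N)
  m <- make_expr(rbind(x, y))
  full <- cor(x, y, method = "spearman")
  dev <- vapply(c(4, 12), function(n) {
    d <- suppressWarnings(generate_subsample_design(N, n))
    rs <- vapply(d$subsamples, function(s) {
      cor(x[s], y[s], method = "spearman")
    }, numeric(1))
    abs(mean(rs, na.rm = TRUE) - full)
  }, numeric(1))
  expect_lt(dev[2], dev[1])
  # and the dispersion of the subsample correlations shrinks with n
  disp <- vapply(c(4, 12), function(n) {
    d <- suppressWarnings(generate_subsample_design(N, n))
    rs <- vapply(d$subsamples, function(s) {
      cor(x[s], y[s], method = "spearman")
    }, numeric(1))
    sd(rs, na.rm = TRUE)
  }, numeric(1))
  expect_lt(disp[2], disp[1])
})
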