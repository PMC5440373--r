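# direct per-SNP exhaustive-count estimator (independent oracle)
oracle_cfdr <- function(p1, p2) {
  n <- length(p1)
  vapply(seq_len(n), function(i) {
    den <- sum(p2 <= p2[i])
    num <- sum(p1 <= p1[i] & p2 <= p2[i])
    min(1, p1[i] * den / num)
  }, numeric(1))
}

test_that("grid values reproduce the exhaustive-count toy example", {
  # stratum p2 <= 0.1 holds 4 SNPs, p1 = {0.001, 0.02, 0.5, 0.9};
  # at p1 = 0.02 the conditional CDF is 2/4 -> cfdr = 0.02/0.5 = 0.04
  pairs <- toy_pairs(p1 = c(0.001, 0.02, 0.5, 0.9),
                     p2 = c(0.05, 0.08, 0.02, 0.1))
  g <- build_cfdr_grid(pairs, grid_size = 81, monotone = FALSE)
  den <- sum(pairs$p2 <= 0.1)
  num <- sum(pairs$p1 <= 0.02 & pairs$p2 <= 0.1)
  direct <- min(1, 0.02 * den / num)
  expect_equal(direct, 0.04)
  # grid and interpolation introduce only resolution error
  expect_equal(lookup_cfdr(g, 0.02, 0.1), direct, tolerance = 0.15)
})

test_that("cfdr is exact at supported grid nodes before monotonization", {
  withr::with_seed(31, pairs <- toy_pairs(p1 = runif(400), p2 = runif(400)))
  g <- build_cfdr_grid(pairs, grid_size = 101, monotone = FALSE)
  # node (i, j) must equal the count ratio evaluated at the node levels,
  # wherever at least one observation supports the cell
  for (idx in list(c(5L, 9L), c(40L, 2L), c(80L, 55L), c(101L, 1L))) {
    i <- idx[1]; j <- idx[2]
    p1n <- 10^(-g$axis1[i]); p2n <- 10^(-g$axis2[j])
    den <- sum(pairs$p2 <= p2n)
    num <- sum(pairs$p1 <= p1n & pairs$p2 <= p2n)
    if (num == 0) next
    want <- min(1, p1n * den / num)
    expect_equal(g$cfdr[i, j], want, tolerance = 1e-12)
    expect_equal(lookup_cfdr(g, p1n, p2n), want, tolerance = 1e-12)
  }
  # beyond a column's observed support the boundary value carries forward
  col <- g$cfdr[, 1L]
  supported <- vapply(seq_along(g$axis1), function(i) {
    sum(pairs$p1 <= 10^(-g$axis1[i])) > 0
  }, logical(1))
  i_star <- max(which(supported))
  if (i_star < length(col)) {
    expect_true(all(col[(i_star + 1):length(col)] == col[i_star]))
  }
})

test_that("lookup interpolates bilinearly and clamps at the boundary", {
  g <- list(axis1 = c(0, 1, 2), axis2 = c(0, 1, 2),
            cfdr = matrix(c(1, 0.5, 0.1,
                            1, 0.04, 0.02,
                            1, 0.06, 0.01), 3, 3),
            direction = "1|2")
  class(g) <- "cfdr_grid"
  # midpoint in log10-p2 between nodes with values 0.04 and 0.06
  expect_equal(lookup_cfdr(g, 0.1, 10^-1.5), 0.05)
  # node exactness
  expect_equal(lookup_cfdr(g, 0.1, 0.1), 0.04)
  # clamped beyond the grid
  expect_equal(lookup_cfdr(g, 1e-10, 1e-10), g$cfdr[3, 3])
  expect_error(lookup_cfdr(g, 0, 0.5), "0, 1")
})

test_that("grid lookup tracks the per-SNP exhaustive estimator on toys", {
  withr::with_seed(32, {
    n <- 1000
    z1 <- rnorm(n) + c(rep(2.5, 100), rep(0, n - 100))
    z2 <- rnorm(n) + c(rep(2.0, 100), rep(0, n - 100))
    pairs <- toy_pairs(p1 = z_to_p(z1), p2 = z_to_p(z2))
  })
  g <- build_cfdr_grid(pairs, grid_size = 201, monotone = FALSE)
  got <- lookup_cfdr(g, pairs$p1, pairs$p2)
  want <- oracle_cfdr(pairs$p1, pairs$p2)
  # agreement within grid-resolution error
  expect_equal(got, want, tolerance = 0.1)
  expect_gt(stats::cor(got, want), 0.999)
})

test_that("a null conditioning trait yields cfdr near 1 (no discoveries)", {
  # with uniform p1 the conditional CDF tends to p1, so the conservative
  # estimator p1/Fhat tends to 1: independence produces no shared signal
  withr::with_seed(33, {
    n <- 1e5
    pairs <- toy_pairs(p1 = runif(n), p2 = runif(n))
  })
  g <- build_cfdr_grid(pairs)
  probe_p1 <- 10^seq(-3, -0.5, length.out = 12)
  for (t2 in c(0.5, 0.05)) {
    v <- lookup_cfdr(g, probe_p1, rep(t2, 12))
    expect_true(all(v > 0.7))
  }
  # and nothing passes the significance threshold
  g21 <- build_cfdr_grid(pairs, direction = "2|1")
  res <- conjunction_fdr(g, g21, pairs)
  expect_equal(sum(res$significant), 0)
})

test_that("cfdr honors its structural invariants", {
  withr::with_seed(34, {
    n <- 5000
    z1 <- rnorm(n, sd = 1.3); z2 <- 0.5 * z1 + rnorm(n, sd = 1.1)
    pairs <- toy_pairs(p1 = z_to_p(z1), p2 = z_to_p(z2))
  })
  g <- build_cfdr_grid(pairs, grid_size = 101)
  expect_true(all(g$cfdr > 0 & g$cfdr <= 1))
  # cfdr(p1 = 1 | anything) = 1
  expect_true(all(abs(g$cfdr[1, ] - 1) < 1e-12))
  # monotone non-increasing along ascending -log10 p1 (non-decreasing in p1)
  expect_true(all(apply(g$cfdr, 2, function(v) all(diff(v) <= 1e-12))))
  # tightening the secondary threshold never increases cfdr
  expect_true(all(t(apply(g$cfdr, 1, function(v) diff(v) <= 1e-12))))
})

test_that("dropping the conditioning recovers the unconditional FDR", {
  withr::with_seed(35, {
    n <- 3000
    pairs <- toy_pairs(p1 = runif(n)^2, p2 = rep(0.5, n))
  })
  g <- build_cfdr_grid(pairs, grid_size = 101, monotone = FALSE)
  # with constant p2 the j = 1 column conditions on everything
  for (p in c(0.01, 0.1, 0.3)) {
    fhat <- mean(pairs$p1 <= p)
    expect_equal(lookup_cfdr(g, p, 1), min(1, p / fhat), tolerance = 0.05)
  }
})

test_that("conjunction FDR is the max rule with a strict threshold", {
  g <- list(axis1 = c(0, 300), axis2 = c(0, 300),
            cfdr = matrix(c(1, 0.01, 1, 0.01), 2, 2), direction = "1|2")
  class(g) <- "cfdr_grid"
  g2 <- g; g2$direction <- "2|1"
  g2$cfdr <- matrix(c(1, 0.03, 1, 0.03), 2, 2)
  pairs <- toy_pairs(p1 = c(1e-300, 1e-300), p2 = c(1e-300, 1e-300))
  res <- conjunction_fdr(g, g2, pairs)
  expect_equal(res$conj_fdr, c(0.03, 0.03))  # max of 0.01 and 0.03
  expect_true(all(res$conj_fdr >= res$cfdr_1g2 &
                    res$conj_fdr >= res$cfdr_2g1))

  # either conditional at 1 forces conjunction 1
  g3 <- g2; g3$cfdr[] <- 1
  expect_equal(conjunction_fdr(g, g3, pairs)$conj_fdr, c(1, 1))

  # strict at the overall threshold: 0.049 significant, 0.050 not
  g4 <- g; g4$cfdr <- matrix(c(1, 0.049, 1, 0.049), 2, 2)
  g5 <- g2; g5$cfdr <- matrix(c(1, 0.001, 1, 0.001), 2, 2)
  expect_true(conjunction_fdr(g4, g5, pairs)$significant[1])
  g6 <- g; g6$cfdr <- matrix(c(1, 0.050, 1, 0.050), 2, 2)
  expect_false(conjunction_fdr(g6, g5, pairs)$significant[1])
})

test_that("conjunction FDR is symmetric in trait order", {
  withr::with_seed(36, {
    n <- 2000
    z1 <- rnorm(n) + c(rep(2, 200), rep(0, n - 200))
    z2 <- rnorm(n) + c(rep(2, 200), rep(0, n - 200))
    pairs <- toy_pairs(p1 = z_to_p(z1), p2 = z_to_p(z2))
  })
  swapped <- copy(pairs)[, `:=`(p1 = p2, p2 = p1, z1 = z2, z2 = z1)]
  g12 <- build_cfdr_grid(pairs, direction = "1|2", grid_size = 101)
  g21 <- build_cfdr_grid(pairs, direction = "2|1", grid_size = 101)
  s12 <- build_cfdr_grid(swapped, direction = "1|2", grid_size = 101)
  s21 <- build_cfdr_grid(swapped, direction = "2|1", grid_size = 101)
  a <- conjunction_fdr(g12, g21, pairs)
  b <- conjunction_fdr(s12, s21, swapped)
  expect_equal(a$conj_fdr, b$conj_fdr, tolerance = 1e-12)
})
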