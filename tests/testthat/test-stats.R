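test_that("circular mean and distance respect the wrap point", {
  expect_equal(circ_dist(3 * pi / 4, -3 * pi / 4), -pi / 2)
  expect_equal(circ_dist(1.3, 1.3), 0)
  # wrap-aware mean: two angles straddling +/- pi average to pi, not 0
  expect_equal(abs(circ_mean(c(-pi + 0.1, pi - 0.1))), pi, tolerance = 1e-10)
  expect_equal(circ_mean(c(0.2, 0.4)), 0.3, tolerance = 1e-10)
  # wrap equivariance: adding 2*pi to any input changes nothing
  set.seed(4)
  a <- runif(20, -pi, pi)
  expect_equal(circ_mean(a), circ_mean(a + 2 * pi), tolerance = 1e-10)
  expect_equal(circ_dist(a + 2 * pi, a[1]), circ_dist(a, a[1]),
               tolerance = 1e-10)
  expect_error(circ_mean(numeric(0)), "empty")
})

test_that("Rayleigh test separates clustered from uniform angles", {
  ident <- rayleigh_test(rep(1.2, 12))
  expect_equal(ident$r, 1)
  expect_lt(ident$p, 1e-4)
  even <- rayleigh_test(seq(-pi, pi, length.out = 13)[-13])
  expect_lt(even$r, 1e-10)
  expect_gt(even$p, 0.99)
  expect_error(rayleigh_test(c(0, 1)), "at least 3")
})

test_that("Rayleigh test rejects at nominal rate under the uniform null", {
  set.seed(11)
  rej <- mean(replicate(2000, rayleigh_test(runif(12, -pi, pi))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.02)
})

# independent oracle: exact null distribution of W by exhausting all 2^n
# sign assignments of the ranks
enumerate_signrank_p <- function(W, n) {
  ranks <- seq_len(n)
  total <- 0L
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    w <- sum(ranks[bitwAnd(bitwShiftR(mask, ranks - 1L), 1L) == 1L])
    total <- total + 1L
    if (w >= W) hits <- hits + 1L
  }
  hits / total
}

test_that("Wilcoxon signed-rank matches the exhaustive sign-enumeration oracle", {
  x <- 1:12 + 0.5
  y <- rep(0, 12)
  res <- wilcoxon_signed_rank(x, y, tail = "greater")
  expect_equal(res$W, 78)
  expect_equal(res$p, 2^-12)
  expect_equal(res$p, enumerate_signrank_p(78, 12))
  # a mid-range W against the same oracle
  set.seed(7)
  d <- c(2.3, -1.1, 0.7, -3.2, 1.9, 0.4, -0.9, 2.8, -1.6, 0.2, 1.2, -2.1)
  res2 <- wilcoxon_signed_rank(d, rep(0, 12), tail = "greater")
  expect_equal(res2$p, enumerate_signrank_p(res2$W, 12))
  # antisymmetry under swapped arguments
  res3 <- wilcoxon_signed_rank(rep(0, 12), d, tail = "greater")
  expect_equal(res3$W, 78 - res2$W)
  expect_error(wilcoxon_signed_rank(1:3, 1:3), "zero")
})

test_that("rank-biserial correlation reproduces its identity and extremes", {
  # 2W/T - 1 at n = 12
  pairs <- list(c(63, 0.615), c(64, 0.641), c(73, 0.872),
                c(53, 0.359), c(65, 0.667), c(61, 0.564))
  for (pw in pairs) {
    expect_equal(round(rank_biserial(pw[1], 12), 3), pw[2])
  }
  expect_equal(rank_biserial(78, 12), 1)
  expect_equal(rank_biserial(39, 12), 0)
  expect_equal(rank_biserial(20, 12), -rank_biserial(78 - 20, 12))
  expect_error(rank_biserial(100, 12), "outside")
})

# brute-force BH step-up: smallest adjusted value consistent with the
# step-up rejection rule
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  adj
}

test_that("FDR adjustment agrees with a brute-force step-up oracle", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.3), 0.3)
  set.seed(21)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(fdr_bh(p), bh_oracle(p))
  }
  # monotone: adjustment never decreases a p value
  p <- runif(15)
  expect_true(all(fdr_bh(p) >= p))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("effect-size and power-analysis arithmetic is reproduced", {
  expect_equal(round(cohens_d_from_t(4.35, 6), 2), 1.78)
  expect_equal(cohens_d_from_t(0, 10), 0)
  expect_equal(cohens_d_from_t(sqrt(7), 7), 1)
  expect_equal(required_sample_size(1.78, method = "noncentral_t"), 4L)
  expect_equal(required_sample_size(0.80, method = "normal_approx"), 10L)
  expect_equal(required_sample_size(10, method = "noncentral_t"), 2L)
  # monotone in d, alpha and power
  expect_gte(required_sample_size(0.5), required_sample_size(1.0))
  expect_gte(required_sample_size(1, alpha = 0.01), required_sample_size(1))
  expect_gte(required_sample_size(1, power = 0.95), required_sample_size(1))
  expect_error(required_sample_size(-1), "d must be")
})
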