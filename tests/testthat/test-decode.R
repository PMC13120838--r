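test_that("ridge logistic matches glmnet on a reference problem", {
  skip_if_not_installed("glmnet")
  set.seed(3)
  n <- 80; p <- 12
  X <- matrix(rnorm(n * p), nrow = n)
  y <- as.integer(runif(n) < plogis(X[, 1] - 0.5 * X[, 2]))
  lambda <- 2
  fit <- wmpulse:::ridge_logistic(X, y, lambda = lambda, balance = FALSE)
  # glmnet minimizes (1/n) loglik + (lambda_g/2) ||w||^2
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                      lambda = lambda / n, standardize = FALSE,
                      thresh = 1e-12)
  expect_equal(fit$weights, as.vector(g$beta), tolerance = 1e-4)
  expect_equal(fit$intercept, as.vector(g$a0), tolerance = 1e-4)
})

test_that("AUC is a rank statistic: ties, monotone invariance, extremes", {
  y <- c(0, 0, 1, 1)
  expect_equal(wmpulse:::auc_rank(c(1, 2, 3, 4), y), 1)
  expect_equal(wmpulse:::auc_rank(c(4, 3, 2, 1), y), 0)
  expect_equal(wmpulse:::auc_rank(c(1, 1, 1, 1), y), 0.5)
  set.seed(8)
  s <- rnorm(40); yy <- rbinom(40, 1, 0.5)
  expect_equal(wmpulse:::auc_rank(s, yy),
               wmpulse:::auc_rank(exp(3 * s) + 2, yy))
})

test_that("a perfectly separating feature yields AUC 1 under the protocol", {
  set.seed(4)
  n <- 60
  y <- rep(0:1, each = n / 2)
  X <- cbind(y * 2 - 1 + rnorm(n, sd = 0.05), matrix(rnorm(n * 5), nrow = n))
  res <- fit_eval_auc(list(X = X, y = y), seed = 2)
  expect_equal(res$auc, 1)
  # pair averaging: 2 * floor(n_class / 2) retained samples per class
  expect_equal(res$n_effective_samples, 2 * 15 + 2 * 15)
  expect_equal(res$config$lambda, 1)
})

test_that("pair averaging discards odd remainders per class", {
  set.seed(5)
  y <- c(rep(0, 13), rep(1, 11))
  X <- matrix(rnorm(24 * 4), nrow = 24)
  res <- fit_eval_auc(list(X = X, y = y), k = 2, reps = 2, seed = 3)
  expect_equal(res$n_effective_samples, 2 * 6 + 2 * 5) # of 13 + 11 inputs
  expect_error(fit_eval_auc(list(X = X[1:3, ], y = c(0, 1, 1)), seed = 1),
               "empties|fewer")
})

test_that("group aggregation takes category medians then participant means", {
  auc <- array(0.5, dim = c(3, 3, 4))
  auc[1, , 2] <- c(0.4, 0.5, 0.9)
  dr <- aggregate_group(auc)
  expect_equal(dr$participant[1, 2], 0.5)
  expect_equal(dr$group, rep(0.5, 4))
  auc[2, 1, 1] <- NA
  expect_error(aggregate_group(auc), "missing")
})

test_that("cluster permutation finds injected effects and nothing in flat curves", {
  flat <- matrix(0.5, nrow = 8, ncol = 12)
  ct0 <- cluster_perm_vs_chance(flat, n_perm = 200, seed = 1)
  expect_length(ct0$clusters, 0)
  set.seed(6)
  auc <- matrix(rnorm(12 * 12, 0.5, 0.05), nrow = 12)
  auc[, 5:8] <- auc[, 5:8] + 0.2
  ct <- cluster_perm_vs_chance(auc, n_perm = 500, seed = 2,
                               times = (1:12) * 0.5)
  expect_gte(length(ct$clusters), 1)
  main <- ct$clusters[[which.max(sapply(ct$clusters, function(cl) abs(cl$mass)))]]
  expect_lte(main$start, 5 + 1)
  expect_gte(main$end, 8 - 1)
  expect_lt(main$p, 0.05)
  expect_error(cluster_perm_vs_chance(auc, n_perm = 50), "n_perm")
  expect_error(cluster_perm_vs_chance(auc[1, , drop = FALSE], n_perm = 200),
               "participants")
})

test_that("paired cluster permutation detects a constant condition shift", {
  set.seed(7)
  B <- matrix(rnorm(12 * 10, 0.5, 0.05), nrow = 12)
  expect_length(cluster_perm_paired(B, B, n_perm = 200, seed = 1)$clusters, 0)
  A <- B + 0.15
  ct <- cluster_perm_paired(A, B, n_perm = 500, seed = 2)
  expect_length(ct$clusters, 1)
  expect_equal(ct$clusters[[1]]$start, 1)
  expect_equal(ct$clusters[[1]]$end, 10)
  expect_lt(ct$clusters[[1]]$p, 0.05)
  expect_error(cluster_perm_paired(A, B[1:6, ], n_perm = 200), "paired")
})

test_that("epoch comparisons report W, exact p and rank-biserial effect size", {
  a <- seq(0.6, 0.71, by = 0.01) # all 12 differences positive
  b <- rep(0.5, 12)
  res <- compare_epochs_wilcoxon(a, b)
  expect_equal(res$W, 78)
  expect_equal(res$p, 1 / 4096)
  expect_equal(res$effect_size, 1)
  expect_equal(round(rank_biserial(63, 12), 3), 0.615)
  # alternating signs with balanced rank mass: W = 39, rbc = 0
  d <- c(1, -2, 3, -4, 5, -6, 7, -8, 9, -10, 11, -12) / 100
  res2 <- compare_epochs_wilcoxon(b + d, b)
  expect_equal(res2$W, 1 + 3 + 5 + 7 + 9 + 11)
  expect_equal(rank_biserial(39, 12), 0)
})
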