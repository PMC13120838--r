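# Ridge-penalized logistic regression fit by IRLS. The penalty is
# 0.5 * lambda * ||w||^2 added to the summed negative log-likelihood; the
# intercept is unpenalized. Class imbalance is handled by weighting
# observations to balanced total class weight and shifting the fitted
# intercept by log(n1/n0) afterwards. With p > n the problem is solved in the
# row space of X (thin SVD), which is exact for a pure L2 penalty.
ridge_logistic <- function(X, y, lambda = 1, balance = TRUE, max_iter = 50,
                           tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_config("ridge_logistic: X/y size mismatch")
  n1 <- sum(y == 1); n0 <- n - n1
  if (n1 == 0 || n0 == 0) stop_config("ridge_logistic: single-class input")
  obs_w <- if (balance) ifelse(y == 1, n / (2 * n1), n / (2 * n0)) else rep(1, n)
  sv <- svd(X)
  r <- sum(sv$d > max(sv$d[1], 1) * 1e-12)
  Z <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
  V <- sv$v[, seq_len(r), drop = FALSE]
  beta <- numeric(r + 1) # intercept first
  Z1 <- cbind(1, Z)
  pen <- diag(c(0, rep(lambda, r)), r + 1)
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(Z1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    Wd <- obs_w * mu * (1 - mu)
    grad <- drop(crossprod(Z1, obs_w * (y - mu))) - drop(pen %*% beta)
    H <- crossprod(Z1 * Wd, Z1) + pen
    delta <- tryCatch(drop(solve(H, grad)), error = function(e) {
      drop(solve(H + diag(1e-8, r + 1), grad))
    })
    beta <- beta + delta
    dev <- -2 * sum(obs_w * (y * log(mu) + (1 - y) * log(1 - mu))) +
      lambda * sum(beta[-1]^2)
    if (abs(dev_old - dev) < tol * (abs(dev) + 1)) break
    dev_old <- dev
  }
  if (any(!is.finite(beta))) {
    stop_config("ridge_logistic: fit did not converge (non-finite coefficients)")
  }
  w <- drop(V %*% beta[-1])
  b0 <- beta[1] + if (balance) log(n1 / n0) else 0
  list(intercept = b0, weights = w,
       predict = function(Xnew) drop(as.matrix(Xnew) %*% w) + b0)
}

# Area under the ROC curve by the rank statistic with midrank ties.
auc_rank <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified k-fold assignment
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated decoding AUC under the study protocol
#'
#' Per repetition: samples are shuffled and averaged in random within-class
#' pairs (odd remainders discarded), split into stratified k folds, each fold
#' z-scored with the training fold's mean/SD only (nested z-scoring), and
#' scored by an L2-penalized logistic regression (penalty 0.5*lambda*||w||^2,
#' unpenalized intercept, imbalance handled by balanced loss plus an intercept
#' shift). The reported AUC is the mean over all folds and repetitions.
#'
#' @param fs a `feature_set` (or any list with X and y).
#' @param k number of folds.
#' @param reps number of repetitions of the fold loop.
#' @param lambda L2 penalty coefficient.
#' @param group size of the random averaging groups (2 = pair averaging;
#'   1 disables).
#' @param seed integer seed.
#' @return list: `auc` (mean), `auc_folds` (reps x k matrix),
#'   `n_effective_samples`, and a config echo.
#' @export
fit_eval_auc <- function(fs, k = 5, reps = 10, lambda = 1, group = 2,
                         seed = 1L) {
  X <- fs$X; y <- fs$y
  with_local_seed(seed, {
    auc_mat <- matrix(NA_real_, nrow = reps, ncol = k)
    n_eff <- NA_integer_
    for (rep_i in seq_len(reps)) {
      if (group > 1L) {
        Xg <- NULL; yg <- NULL
        for (cl in 0:1) {
          idx <- sample(which(y == cl))
          m <- length(idx) %/% group
          if (m < 1L) stop_config("fit_eval_auc: class %d empties after averaging", cl)
          idx <- idx[seq_len(m * group)]
          gid <- rep(seq_len(m), each = group)
          Xc <- rowsum(X[idx, , drop = FALSE], gid) / group
          Xg <- rbind(Xg, Xc)
          yg <- c(yg, rep(cl, m))
        }
      } else {
        Xg <- X; yg <- y
      }
      if (min(table(factor(yg, levels = 0:1))) < k) {
        stop_config("fit_eval_auc: fewer samples per class than folds")
      }
      # per the protocol's accounting: retained original samples per class,
      # i.e. group * floor(n_class / group) summed over classes
      n_eff <- length(yg) * group
      fold <- stratified_folds(yg, k)
      for (f in seq_len(k)) {
        tr <- fold != f; te <- !tr
        mu <- colMeans(Xg[tr, , drop = FALSE])
        sd_ <- apply(Xg[tr, , drop = FALSE], 2, stats::sd)
        sd_[sd_ == 0 | !is.finite(sd_)] <- 1
        Xtr <- sweep(sweep(Xg[tr, , drop = FALSE], 2, mu), 2, sd_, "/")
        Xte <- sweep(sweep(Xg[te, , drop = FALSE], 2, mu), 2, sd_, "/")
        fit <- ridge_logistic(Xtr, yg[tr], lambda = lambda)
        auc_mat[rep_i, f] <- auc_rank(fit$predict(Xte), yg[te])
      }
    }
    list(auc = mean(auc_mat, na.rm = TRUE), auc_folds = auc_mat,
         n_effective_samples = n_eff,
         config = list(k = k, reps = reps, lambda = lambda, group = group,
                       seed = seed))
  })
}

#' Aggregate per-category AUCs to participant and group level
#'
#' The participant value at each timepoint is the median across the stimulus
#' categories; the group curve is the mean across participants.
#'
#' @param auc_cat numeric array participants x categories x timepoints (a
#'   matrix is treated as a single timepoint).
#' @return list of class `decode_result`: `participant` (participants x
#'   timepoints median-across-category AUC), `group` (timepoint vector).
#' @export
aggregate_group <- function(auc_cat) {
  if (length(dim(auc_cat)) == 2L) {
    auc_cat <- array(auc_cat, dim = c(dim(auc_cat), 1L))
  }
  if (anyNA(auc_cat)) stop_config("aggregate_group: missing category AUC")
  d <- dim(auc_cat)
  part <- apply(auc_cat, c(1, 3), stats::median)
  part <- matrix(part, nrow = d[1])
  structure(list(participant = part, group = colMeans(part)),
            class = "decode_result")
}
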