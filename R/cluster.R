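# one-sample t statistics per column (participants x timepoints input)
col_tstats <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  s <- sqrt(pmax(0, colSums(d^2) - n * m^2) / (n - 1))
  s[s == 0] <- .Machine$double.eps
  m / (s / sqrt(n))
}

# contiguous runs of supra-threshold t of consistent sign
find_clusters <- function(t_stats, t_crit) {
  sig <- abs(t_stats) > t_crit
  out <- list()
  i <- 1L; nt <- length(t_stats)
  while (i <= nt) {
    if (sig[i]) {
      s <- sign(t_stats[i])
      j <- i
      while (j < nt && sig[j + 1L] && sign(t_stats[j + 1L]) == s) j <- j + 1L
      out[[length(out) + 1L]] <- list(start = i, end = j,
                                      mass = sum(t_stats[i:j]))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

cluster_perm_core <- function(d, n_perm, seed, cluster_alpha, times) {
  n <- nrow(d); nt <- ncol(d)
  if (n < 2L) stop_config("cluster permutation: need >= 2 participants")
  if (n_perm < 100L) stop_config("cluster permutation: n_perm must be >= 100")
  t_crit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  t_obs <- col_tstats(d)
  clusters <- find_clusters(t_obs, t_crit)
  max_mass <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      dp <- d * sample(c(-1, 1), n, replace = TRUE)
      cl <- find_clusters(col_tstats(dp), t_crit)
      if (length(cl)) max(abs(vapply(cl, `[[`, 0, "mass"))) else 0
    }, 0)
  })
  for (i in seq_along(clusters)) {
    clusters[[i]]$p <- (1 + sum(max_mass >= abs(clusters[[i]]$mass))) /
      (1 + n_perm)
    if (!is.null(times)) {
      clusters[[i]]$start_s <- times[clusters[[i]]$start]
      clusters[[i]]$end_s <- times[clusters[[i]]$end]
    }
  }
  structure(list(clusters = clusters, t_stats = t_obs, t_crit = t_crit,
                 n_perm = n_perm, alternative = "two.sided"),
            class = "cluster_test")
}

#' Cluster-based permutation test of AUC curves against chance
#'
#' Timepoint-wise one-sample t statistics on (AUC - null), clusters formed
#' from contiguous supra-threshold runs of consistent sign (cluster-forming
#' threshold: two-tailed alpha on the t statistic), cluster mass = summed t,
#' and a max-mass null from random per-participant sign flips. Two-tailed via
#' the absolute mass.
#'
#' @param auc matrix participants x timepoints.
#' @param null chance level subtracted before testing (0.5 for AUC).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param cluster_alpha two-tailed alpha of the cluster-forming threshold.
#' @param times optional timepoint axis (s) echoed into the clusters.
#' @return object of class `cluster_test`: clusters (start, end, mass, p),
#'   t_stats, t_crit, n_perm.
#' @export
cluster_perm_vs_chance <- function(auc, null = 0.5, n_perm = 5000, seed = 1L,
                                   cluster_alpha = 0.05, times = NULL) {
  cluster_perm_core(as.matrix(auc) - null, n_perm, seed, cluster_alpha, times)
}

#' Paired cluster-based permutation test between two conditions
#'
#' As [cluster_perm_vs_chance()] on the paired difference A - B; the null
#' randomly swaps each participant's condition labels (equivalent to sign
#' flips of the difference curves).
#'
#' @param aucA,aucB matrices participants x timepoints, paired by row.
#' @inheritParams cluster_perm_vs_chance
#' @return a `cluster_test`.
#' @export
cluster_perm_paired <- function(aucA, aucB, n_perm = 5000, seed = 1L,
                                cluster_alpha = 0.05, times = NULL) {
  aucA <- as.matrix(aucA); aucB <- as.matrix(aucB)
  if (!all(dim(aucA) == dim(aucB))) {
    stop_config("cluster_perm_paired: inputs must be paired (same dimensions)")
  }
  cluster_perm_core(aucA - aucB, n_perm, seed, cluster_alpha, times)
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("cluster_test: %d cluster(s), t_crit = %.2f, %d permutations\n",
              length(x$clusters), x$t_crit, x$n_perm))
  for (cl in x$clusters) {
    cat(sprintf("  [%d, %d] mass = %.2f, p = %.4f\n",
                cl$start, cl$end, cl$mass, cl$p))
  }
  invisible(x)
}

#' Between-epoch comparison of decoding AUC
#'
#' One-tailed Wilcoxon signed-rank test that paired AUC values in epoch A
#' exceed those in epoch B, with the rank-biserial correlation as effect size.
#'
#' @param aucA,aucB paired per-participant AUC values.
#' @param tail alternative direction, default "greater" (A > B).
#' @return a stat-result list from [wilcoxon_signed_rank()].
#' @export
compare_epochs_wilcoxon <- function(aucA, aucB, tail = "greater") {
  wilcoxon_signed_rank(aucA, aucB, tail = tail)
}
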