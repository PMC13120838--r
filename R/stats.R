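#' Circular mean
#'
#' Mean direction of a set of angles, computed as the argument of the mean
#' unit phasor. The result lies in (-pi, pi].
#'
#' @param angles numeric vector of angles in radians.
#' @return scalar angle in radians.
#' @export
circ_mean <- function(angles) {
  if (length(angles) == 0L || anyNA(angles)) {
    stop_config("circ_mean: empty or missing input")
  }
  wrap_angle(Arg(mean(exp(1i * angles))))
}

#' Circular (wrapped) difference
#'
#' Signed angular difference a - b wrapped to (-pi, pi]. Antisymmetric:
#' circ_dist(a, b) == -circ_dist(b, a) up to the wrap point.
#'
#' @param a,b angles in radians (recycled).
#' @return wrapped differences in radians.
#' @export
circ_dist <- function(a, b) wrap_angle(a - b)

# Resultant vector length of a set of angles (0 = uniform, 1 = identical).
resultant_length <- function(angles) Mod(mean(exp(1i * angles)))

#' Rayleigh test of circular uniformity
#'
#' Tests whether angles cluster around a common direction. Returns the
#' resultant vector length r and a p value from the standard finite-sample
#' approximation p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n)) with
#' R = n * r.
#'
#' @param angles numeric vector of angles in radians, length >= 3.
#' @return list with elements `r`, `p`, `n`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 3L) stop_config("rayleigh_test: need at least 3 angles")
  r <- resultant_length(angles)
  R <- n * r
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(r = r, p = min(max(p, .Machine$double.xmin), 1), n = n)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' W is the sum of the ranks of the positive differences x - y after dropping
#' zero differences. For n <= 25 without ties among |differences| the p value
#' is exact (full sign-flip null distribution); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y paired numeric vectors.
#' @param tail one of "greater" (x > y), "less", "two.sided".
#' @return list: statistic `W`, `p`, `n` (nonzero pairs), `effect_size`
#'   (rank-biserial correlation), `tail`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  if (length(x) != length(y)) stop_config("wilcoxon_signed_rank: unpaired input")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop_config("wilcoxon_signed_rank: all differences are zero")
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25L && !ties) {
    method <- "exact"
    # psignrank gives the exact distribution of W under random signs
    p_greater <- stats::psignrank(W - 1, n, lower.tail = FALSE)
    p_less <- stats::psignrank(W, n)
  } else {
    method <- "normal approximation"
    mu <- n * (n + 1) / 4
    tie_tab <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    sigma <- sqrt(sigma2)
    p_greater <- stats::pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
    p_less <- stats::pnorm((W - mu + 0.5) / sigma)
  }
  p <- switch(tail,
    greater = p_greater,
    less = p_less,
    two.sided = min(1, 2 * min(p_greater, p_less))
  )
  list(
    statistic = "W", W = W, p = min(max(p, .Machine$double.xmin), 1), n = n,
    effect_size = rank_biserial(W, n), tail = tail, method = method
  )
}

#' Rank-biserial correlation from a signed-rank statistic
#'
#' Matched-pairs rank-biserial effect size rbc = 2W/T - 1 where
#' T = n(n+1)/2 is the total rank sum. Ranges over [-1, 1]; 0 means positive
#' and negative ranks balance exactly.
#'
#' @param W signed-rank statistic (sum of positive ranks).
#' @param n number of nonzero paired differences.
#' @return rank-biserial correlation in [-1, 1].
#' @export
rank_biserial <- function(W, n) {
  T_ <- n * (n + 1) / 2
  if (W < 0 || W > T_) stop_config("rank_biserial: W outside [0, n(n+1)/2]")
  2 * W / T_ - 1
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values controlling the false discovery rate. Thin
#' validated wrapper over the standard step-up procedure.
#'
#' @param pvals numeric vector of p values in [0, 1].
#' @return adjusted p values, same length and order as the input.
#' @export
fdr_bh <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop_config("fdr_bh: p values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Cohen's d from a one-sample t statistic
#'
#' d = t / sqrt(n), the standardized mean difference implied by a one-sample
#' (or paired) t statistic with n observations.
#'
#' @param t t statistic.
#' @param n sample size (>= 2).
#' @return Cohen's d.
#' @export
cohens_d_from_t <- function(t, n) {
  if (n < 2) stop_config("cohens_d_from_t: need n >= 2")
  t / sqrt(n)
}

#' Required sample size for a one-sample t test
#'
#' Smallest n achieving the target power for effect size d at level alpha.
#' `method = "noncentral_t"` evaluates power exactly from the noncentral t
#' distribution (ncp = d * sqrt(n), df = n - 1); `method = "normal_approx"`
#' uses ceiling(((z_{1-alpha} + z_{power}) / d)^2), the large-sample formula
#' (one-tailed; for two-tailed, alpha/2).
#'
#' @param d Cohen's d (> 0).
#' @param alpha significance level.
#' @param power target power.
#' @param tail "one" or "two".
#' @param method "noncentral_t" or "normal_approx".
#' @return required sample size (integer).
#' @export
required_sample_size <- function(d, alpha = 0.05, power = 0.80,
                                 tail = c("one", "two"),
                                 method = c("noncentral_t", "normal_approx")) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  if (d <= 0) stop_config("required_sample_size: d must be > 0")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop_config("required_sample_size: alpha and power must lie in (0, 1)")
  }
  a <- if (tail == "one") alpha else alpha / 2
  if (method == "normal_approx") {
    return(as.integer(ceiling(((stats::qnorm(1 - a) + stats::qnorm(power)) / d)^2)))
  }
  for (n in 2:100000) {
    crit <- stats::qt(1 - a, df = n - 1)
    pw <- stats::pt(crit, df = n - 1, ncp = d * sqrt(n), lower.tail = FALSE)
    if (tail == "two") {
      pw <- pw + stats::pt(-crit, df = n - 1, ncp = d * sqrt(n))
    }
    if (pw >= power) return(as.integer(n))
  }
  stop_config("required_sample_size: no n <= 1e5 reaches the target power")
}
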