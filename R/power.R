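#' Relative band power around an event
#'
#' For each trial of a channel-averaged epoch set, takes the 1 s segment
#' preceding (side = "pre") or following (side = "post") the lock event,
#' applies a Hanning taper, computes the FFT power spectrum at 1 Hz
#' resolution, and returns the proportion of total 1-45 Hz power falling in
#' the band (same integer-bin edge convention as the decoding features).
#'
#' @param ts a `trial_series` locked to the event (t = 0).
#' @param side "pre" ([-1, 0) s) or "post" ([0, 1) s).
#' @param band a `band_def`.
#' @param total_range denominator frequency range in Hz.
#' @return numeric vector of per-trial relative power in [0, 1].
#' @export
relative_band_power <- function(ts, side = c("post", "pre"), band,
                                total_range = c(1, 45)) {
  side <- match.arg(side)
  fs <- ts$fs
  nseg <- round(fs) # 1 s
  i0 <- which.min(abs(ts$time))
  idx <- if (side == "pre") (i0 - nseg):(i0 - 1L) else i0:(i0 + nseg - 1L)
  if (min(idx) < 1L || max(idx) > ncol(ts$data)) {
    stop_config("relative_band_power: 1 s segment truncated at the epoch edge")
  }
  taper <- hann_taper(nseg)
  seg <- ts$data[, idx, drop = FALSE] * rep(taper, each = nrow(ts$data))
  spec <- Mod(stats::mvfft(t(seg)))^2 # freq x trials, bin k+1 = k Hz
  all_bins <- total_range[1]:total_range[2]
  bbins <- band_bins(band, all_bins)
  if (!length(bbins)) stop_config("relative_band_power: band has no bins")
  colSums(spec[bbins + 1L, , drop = FALSE]) /
    colSums(spec[all_bins + 1L, , drop = FALSE])
}

# shared two-tailed permutation p value machinery
perm_pvalue <- function(obs, perm, n_iter) {
  p_hi <- mean(perm >= obs)
  p_lo <- mean(perm <= obs)
  max(1 / n_iter, min(1, 2 * min(p_hi, p_lo)))
}

#' Pre/post permutation test of band power
#'
#' Observed statistic mean(post) - mean(pre); null by randomly flipping each
#' trial's pre/post labels; two-tailed p value.
#'
#' @param pre,post per-trial relative power, equal length.
#' @param n_iter permutation iterations.
#' @param seed integer seed.
#' @return list: `p`, `observed`, `n_iter`.
#' @export
pre_post_power_test <- function(pre, post, n_iter = 5000, seed = 1L) {
  if (length(pre) != length(post)) {
    stop_config("pre_post_power_test: unequal trial counts")
  }
  if (length(pre) < 10L) {
    warning("pre_post_power_test: fewer than 10 trials (low power)",
            call. = FALSE)
  }
  d <- post - pre
  n <- length(d)
  obs <- mean(d)
  perm <- with_local_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_iter * n, replace = TRUE), nrow = n_iter)
    drop(signs %*% d) / n
  })
  list(p = perm_pvalue(obs, perm, n_iter), observed = obs, n_iter = n_iter)
}

#' Between-condition permutation test of band power
#'
#' Pools the spTMS-present and spTMS-absent trial values, permutes the
#' condition labels preserving the original group sizes, and tests the mean
#' difference (with minus without), two-tailed.
#'
#' @param with_tms,without_tms per-trial values for the two conditions.
#' @param n_iter permutation iterations.
#' @param seed integer seed.
#' @return list: `p`, `observed`, `n_iter`.
#' @export
between_condition_power_test <- function(with_tms, without_tms, n_iter = 5000,
                                         seed = 1L) {
  n1 <- length(with_tms); n0 <- length(without_tms)
  if (n1 < 2L || n0 < 2L) {
    stop_config("between_condition_power_test: need >= 2 trials per condition")
  }
  pooled <- c(with_tms, without_tms)
  obs <- mean(with_tms) - mean(without_tms)
  perm <- with_local_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      idx <- sample.int(n1 + n0, n1)
      mean(pooled[idx]) - mean(pooled[-idx])
    }, 0)
  })
  list(p = perm_pvalue(obs, perm, n_iter), observed = obs, n_iter = n_iter)
}
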