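#' Instantaneous phase of band-filtered trials
#'
#' Per trial: order-4 zero-phase (forward-backward) Butterworth bandpass into
#' the band, analytic signal via the Hilbert transform, phase as its argument.
#' Intended for 4 s channel-averaged epochs centered on the lock event.
#'
#' @param ts a `trial_series` (channel-averaged epochs, event at t = 0).
#' @param band a `band_def`.
#' @return object of class `phase_set`: phase matrix (trials x time, radians
#'   in (-pi, pi]), time, fs, band name, trial_meta.
#' @export
instantaneous_phase <- function(ts, band) {
  ny <- ts$fs / 2
  if (band$f_high >= ny) stop_config("instantaneous_phase: band exceeds Nyquist")
  bf <- signal::butter(4, c(band$f_low, band$f_high) / ny, type = "pass")
  ph <- ts$data
  for (r in seq_len(nrow(ph))) {
    filt <- signal::filtfilt(bf, ts$data[r, ])
    ph[r, ] <- wrap_angle(Arg(analytic_signal(filt)))
  }
  structure(list(phase = ph, time = ts$time, fs = ts$fs, band = band$name,
                 band_def = band, trial_meta = ts$trial_meta),
            class = "phase_set")
}

#' @export
print.phase_set <- function(x, ...) {
  cat(sprintf("phase_set: %s band, %d trials x %d samples @ %g Hz\n",
              x$band, nrow(x$phase), ncol(x$phase), x$fs))
  invisible(x)
}

#' Across-trial phase-locking value time course
#'
#' PLV(t) = |mean over trials of exp(i * phase)|, in [0, 1].
#'
#' @param ps a `phase_set`.
#' @return numeric vector over the time axis.
#' @export
plv_timecourse <- function(ps) {
  if (nrow(ps$phase) < 2L) {
    warning("plv_timecourse: single trial; PLV is degenerately 1", call. = FALSE)
  }
  Mod(colMeans(exp(1i * ps$phase)))
}

#' Analysis window specification
#'
#' @param band band name.
#' @param event_class "cue" or "sptms".
#' @param n_cycles integer number of oscillatory cycles in the window.
#' @param onset window onset after the event, seconds.
#' @param length window length, seconds.
#' @param selection_t group t statistic that selected the window (if any).
#' @return object of class `window_spec`.
#' @export
window_spec <- function(band, event_class, n_cycles, onset, length,
                        selection_t = NA_real_) {
  structure(list(band = band, event_class = event_class, n_cycles = n_cycles,
                 onset = onset, length = length, selection_t = selection_t),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("window_spec: %s/%s, %d cycles, onset %.0f ms, length %.0f ms (t = %.2f)\n",
              x$band, x$event_class, x$n_cycles, 1000 * x$onset,
              1000 * x$length, x$selection_t))
  invisible(x)
}

# sample indices of the post window and the equal-length pre window ending at
# the event, for a phase/trial series time axis
window_indices <- function(time, fs, w) {
  i0 <- which.min(abs(time)) # lock sample (t = 0)
  nw <- round(w$length * fs)
  post0 <- i0 + round(w$onset * fs)
  post <- post0:(post0 + nw - 1L)
  pre <- (i0 - nw):(i0 - 1L)
  if (min(pre) < 1L || max(post) > length(time)) {
    stop_config("window outside the epoch (onset %.0f ms, length %.0f ms)",
                1000 * w$onset, 1000 * w$length)
  }
  list(pre = pre, post = post)
}

#' Frequency-adaptive sliding-window selection
#'
#' Scans candidate post-event windows - integer numbers of oscillatory cycles
#' (2-4 for theta/alpha, 3-6 for the beta bands; cycle duration from the band
#' midpoint frequency) by onsets on the 10 ms grid within the post period
#' (0-500 ms for cues, 30-500 ms for spTMS) - and for each computes every
#' participant's post-minus-pre PLV difference against an equal-length
#' pre-event baseline ending at the event. Returns the window with the
#' maximum absolute group one-sample t statistic; ties break to the earliest
#' onset, then the fewest cycles.
#'
#' @param ps_list list of `phase_set`, one per participant (data pooled over
#'   the conditions of the event class).
#' @param band a `band_def`.
#' @param event_class "cue" or "sptms" (sets the minimum onset: 0 vs 30 ms).
#' @param post_max latest candidate onset, seconds.
#' @return a `window_spec` with `selection_t` filled in.
#' @export
select_window <- function(ps_list, band, event_class = c("sptms", "cue"),
                          post_max = 0.5) {
  event_class <- match.arg(event_class)
  if (length(ps_list) < 2L) stop_config("select_window: need >= 2 participants")
  fs <- ps_list[[1]]$fs
  time <- ps_list[[1]]$time
  onset_min <- if (event_class == "sptms") 0.030 else 0
  # per-participant PLV time courses with cumulative sums for window means
  plv_cum <- lapply(ps_list, function(ps) cumsum(c(0, plv_timecourse(ps))))
  win_mean <- function(cum, idx) (cum[max(idx) + 1L] - cum[min(idx)]) / length(idx)
  fc <- band_center(band)
  best <- NULL
  for (ncyc in band_cycle_range(band)) {
    len <- floor((ncyc / fc) / 0.01) * 0.01 # cycles -> 10 ms grid, rounded down
    nw <- round(len * fs)
    if (nw < 1L) next
    for (onset in seq(onset_min, post_max, by = 0.01)) {
      idx <- tryCatch(window_indices(time, fs, list(onset = onset, length = len)),
                      error = function(e) NULL)
      if (is.null(idx)) next
      diffs <- vapply(plv_cum, function(cum) {
        win_mean(cum, idx$post) - win_mean(cum, idx$pre)
      }, 0)
      s <- stats::sd(diffs)
      t_stat <- if (s == 0) 0 else mean(diffs) / (s / sqrt(length(diffs)))
      if (is.null(best) || abs(t_stat) > abs(best$selection_t) + 1e-12) {
        best <- window_spec(band$name, event_class, ncyc, onset, len, t_stat)
      }
    }
  }
  if (is.null(best)) stop_config("select_window: no candidate window fits the epoch")
  best
}

#' Within-participant PLV change
#'
#' Mean across-trial PLV over the post-event window minus the same over the
#' equal-length pre-event window; in [-1, 1].
#'
#' @param ps a `phase_set` (one participant).
#' @param w a `window_spec`.
#' @return scalar PLV change.
#' @export
wp_plv_change <- function(ps, w) {
  idx <- window_indices(ps$time, ps$fs, w)
  plv <- plv_timecourse(ps)
  mean(plv[idx$post]) - mean(plv[idx$pre])
}

#' Mean phase-angle shift
#'
#' Per trial: circular mean phase in the post window minus circular mean
#' phase in the pre window, wrapped to (-pi, pi]; the participant value is
#' the circular mean of the trial shifts. The resultant length of the trial
#' shifts is retained as a confidence diagnostic; below `min_confidence` the
#' value is flagged low-confidence.
#'
#' @param ps a `phase_set` (one participant).
#' @param w a `window_spec`.
#' @param min_confidence resultant-length threshold for the flag.
#' @return list: `shift` (radians), `confidence_r`, `low_confidence`.
#' @export
mean_phase_shift <- function(ps, w, min_confidence = 0.1) {
  idx <- window_indices(ps$time, ps$fs, w)
  shifts <- apply(ps$phase, 1, function(row) {
    circ_dist(circ_mean(row[idx$post]), circ_mean(row[idx$pre]))
  })
  r <- resultant_length(shifts)
  list(shift = circ_mean(shifts), confidence_r = r,
       low_confidence = r < min_confidence)
}

#' Intersubject PLV of participant phase shifts
#'
#' Resultant vector length of the participants' mean phase shifts (0 = no
#' cross-participant alignment, 1 = perfect), with a bootstrap standard error
#' from participant resampling.
#'
#' @param shifts participant phase shifts, radians (n >= 3).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return list: `r`, `se`, `n`, `n_boot`.
#' @export
intersubject_plv <- function(shifts, n_boot = 1000, seed = 1L) {
  n <- length(shifts)
  if (n < 3L) stop_config("intersubject_plv: need >= 3 participants")
  r <- resultant_length(shifts)
  se <- with_local_seed(seed, {
    stats::sd(vapply(seq_len(n_boot), function(i) {
      resultant_length(shifts[sample.int(n, n, replace = TRUE)])
    }, 0))
  })
  list(r = r, se = se, n = n, n_boot = n_boot)
}

#' Phase measures for one condition
#'
#' Convenience wrapper computing, per participant, the within-participant PLV
#' change and mean phase shift in a fixed window, plus the group intersubject
#' PLV.
#'
#' @param ps_list list of `phase_set`, one per participant.
#' @param w a `window_spec`.
#' @param seed seed for the intersubject bootstrap.
#' @return object of class `phase_measures`: vectors `wp_plv_change`,
#'   `mean_shift`, `confidence_r`, logical `low_confidence`; `intersubject`
#'   (list r/se); `window`; `normalized` flag.
#' @export
compute_phase_measures <- function(ps_list, w, seed = 1L) {
  plv <- vapply(ps_list, wp_plv_change, 0, w = w)
  sh <- lapply(ps_list, mean_phase_shift, w = w)
  shifts <- vapply(sh, `[[`, 0, "shift")
  isp <- if (length(shifts) >= 3L) intersubject_plv(shifts, seed = seed) else
    list(r = NA_real_, se = NA_real_, n = length(shifts), n_boot = 0L)
  structure(list(
    wp_plv_change = plv,
    mean_shift = shifts,
    confidence_r = vapply(sh, `[[`, 0, "confidence_r"),
    low_confidence = vapply(sh, `[[`, TRUE, "low_confidence"),
    intersubject = isp,
    window = w, normalized = FALSE
  ), class = "phase_measures")
}

#' Normalize spTMS-present phase measures against spTMS-absent trials
#'
#' PLV changes are normalized by arithmetic subtraction and mean shifts by
#' circular difference; both conditions must have been computed in the same
#' window (the window identified on spTMS-present trials is reused for the
#' absent trials).
#'
#' @param present,absent `phase_measures` from [compute_phase_measures()].
#' @return normalized `phase_measures`.
#' @export
normalize_vs_absent <- function(present, absent) {
  wa <- present$window; wb <- absent$window
  if (!identical(wa[c("band", "n_cycles", "onset", "length")],
                 wb[c("band", "n_cycles", "onset", "length")])) {
    stop_config("normalize_vs_absent: mismatched analysis windows")
  }
  out <- present
  out$wp_plv_change <- present$wp_plv_change - absent$wp_plv_change
  out$mean_shift <- circ_dist(present$mean_shift, absent$mean_shift)
  out$intersubject <- if (length(out$mean_shift) >= 3L) {
    intersubject_plv(out$mean_shift,
                     n_boot = max(present$intersubject$n_boot, 100L))
  } else list(r = NA_real_, se = NA_real_, n = length(out$mean_shift),
              n_boot = 0L)
  out$normalized <- TRUE
  out
}

#' Paired permutation test
#'
#' Null distribution by randomly flipping each participant's condition labels
#' and recomputing the mean difference; the two-tailed p value is twice the
#' smaller tail proportion (inclusive), floored at 1/n_iter and capped at 1.
#' For circular measures the per-participant difference is the wrapped
#' circular distance and the statistic its mean.
#'
#' @param a,b paired per-participant measures.
#' @param n_iter permutation iterations (>= 100).
#' @param seed integer seed.
#' @param circular treat inputs as angles?
#' @return list: `p`, `observed`, `n_iter`.
#' @export
paired_permutation <- function(a, b, n_iter = 5000, seed = 1L,
                               circular = FALSE) {
  if (length(a) != length(b)) stop_config("paired_permutation: unpaired input")
  if (n_iter < 100L) stop_config("paired_permutation: n_iter must be >= 100")
  d <- if (circular) circ_dist(a, b) else a - b
  n <- length(d)
  obs <- mean(d)
  perm <- with_local_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_iter * n, replace = TRUE),
                    nrow = n_iter)
    drop(signs %*% d) / n
  })
  p_hi <- mean(perm >= obs)
  p_lo <- mean(perm <= obs)
  p <- max(1 / n_iter, min(1, 2 * min(p_hi, p_lo)))
  list(p = p, observed = obs, n_iter = n_iter)
}

#' Time-resolved phase-consistency analysis
#'
#' Ten 50 ms windows with onsets 50-500 ms post-event. In each window every
#' participant contributes a mean phase angle (circular mean over trials of
#' the per-trial circular mean within the window); clustering of these angles
#' is tested with the Rayleigh test, FDR-corrected over the 10 windows. With
#' a paired second condition, the between-condition difference in resultant
#' length is tested by permutation (condition labels swapped per participant),
#' two-tailed, FDR-corrected over the 10 windows.
#'
#' @param ps_a list of `phase_set` per participant, condition A.
#' @param ps_b optional paired list for condition B.
#' @param n_iter permutation iterations for the between test.
#' @param seed integer seed.
#' @return object of class `time_resolved_consistency`: data.frame `windows`
#'   with onset_s, r_a (and r_b, diff), p_rayleigh_a (FDR), and p_between
#'   (FDR) when B is supplied.
#' @export
time_resolved_consistency <- function(ps_a, ps_b = NULL, n_iter = 1000,
                                      seed = 1L) {
  onsets <- seq(0.05, 0.50, by = 0.05)
  width <- 0.05
  participant_angle <- function(ps, onset) {
    idx <- window_indices(ps$time, ps$fs, list(onset = onset, length = width))
    circ_mean(apply(ps$phase[, idx$post, drop = FALSE], 1, circ_mean))
  }
  angles_for <- function(ps_list) {
    vapply(onsets, function(on) {
      vapply(ps_list, participant_angle, 0, onset = on)
    }, numeric(length(ps_list))) # participants x windows
  }
  ang_a <- angles_for(ps_a)
  n <- nrow(ang_a)
  ray_a <- apply(ang_a, 2, function(a) unlist(rayleigh_test(a)[c("r", "p")]))
  win <- data.frame(onset_s = onsets, r_a = ray_a["r", ],
                    p_rayleigh_a = fdr_bh(ray_a["p", ]))
  if (!is.null(ps_b)) {
    if (length(ps_b) != length(ps_a)) {
      stop_config("time_resolved_consistency: conditions must be paired")
    }
    ang_b <- angles_for(ps_b)
    ray_b <- apply(ang_b, 2, function(a) unlist(rayleigh_test(a)[c("r", "p")]))
    win$r_b <- ray_b["r", ]
    win$p_rayleigh_b <- fdr_bh(ray_b["p", ])
    obs <- win$r_a - win$r_b
    p_between <- with_local_seed(seed, {
      perm <- matrix(0, nrow = n_iter, ncol = length(onsets))
      for (it in seq_len(n_iter)) {
        swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
        pa <- ang_a; pa[swap, ] <- ang_b[swap, ]
        pb <- ang_b; pb[swap, ] <- ang_a[swap, ]
        perm[it, ] <- apply(pa, 2, resultant_length) -
          apply(pb, 2, resultant_length)
      }
      vapply(seq_along(onsets), function(j) {
        p_hi <- mean(perm[, j] >= obs[j])
        p_lo <- mean(perm[, j] <= obs[j])
        max(1 / n_iter, min(1, 2 * min(p_hi, p_lo)))
      }, 0)
    })
    win$r_diff <- obs
    win$p_between <- fdr_bh(p_between)
  }
  structure(list(windows = win, n = n, n_iter = n_iter),
            class = "time_resolved_consistency")
}
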