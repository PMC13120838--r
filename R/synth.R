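#' Expected phase-locking value of a von Mises phase reset
#'
#' Mean resultant length of phases drawn from a von Mises distribution with
#' concentration kappa: the Bessel-function ratio I1(kappa)/I0(kappa). This is
#' the asymptotic across-trial PLV at the reset latency and serves as the
#' analytic oracle for phase-reset recovery.
#'
#' @param kappa von Mises concentration, >= 0.
#' @return expected PLV in [0, 1).
#' @export
expected_plv <- function(kappa) {
  if (any(kappa < 0)) stop_config("expected_plv: kappa must be >= 0")
  # exponentially scaled Bessel ratio is stable for large kappa
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

# Unit-SD narrowband noise: white noise bandpass filtered into [f_lo, f_hi]
# with an order-4 zero-phase Butterworth. Returns a real vector of length n.
narrowband_source <- function(n, f_lo, f_hi, fs) {
  bf <- signal::butter(4, c(f_lo, f_hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

# 1/f^a background noise of length n with unit SD, by spectral shaping.
pink_noise <- function(n, exponent, fs) {
  n2 <- next_fast_len(n)
  X <- stats::fft(stats::rnorm(n2))
  f <- c(1, seq_len(n2 - 1)) # avoid dividing DC by zero
  f <- pmin(f, n2 - f + 1) # mirror for negative frequencies
  X <- X / f^(exponent / 2)
  x <- Re(stats::fft(X, inverse = TRUE) / n2)[seq_len(n)]
  x / stats::sd(x)
}

# Events in `schedule` that reset a band, given its reset_kappa map. Keys are
# exact event labels, except that key "sptms" matches any sptms_* label.
band_reset_events <- function(schedule, band) {
  keys <- names(band$reset_kappa)
  if (is.null(keys) || length(keys) == 0L) return(NULL)
  out <- NULL
  for (key in keys) {
    hit <- if (key == "sptms") startsWith(schedule$event_label, "sptms") else
      schedule$event_label == key
    if (any(hit)) {
      sel <- schedule[hit, c("event_label", "latency_s")]
      sel$kappa <- band$reset_kappa[[key]]
      out <- rbind(out, sel)
    }
  }
  if (!is.null(out)) out <- out[order(out$latency_s), ]
  out
}

# Phase-rotation offset implementing von Mises resets. Each reset at sample k
# draws a target phase theta ~ vonMises(reset_phase, kappa); the analytic
# signal is rotated so that its phase at k equals theta exactly, with the
# rotation ramped in linearly over the preceding oscillatory cycle so neither
# amplitude nor phase jumps discontinuously. Returned as the cumulative sum of
# per-sample rotation increments, which holds each reset's rotation constant
# after its ramp completes.
apply_phase_resets <- function(z, resets, band, fs, n) {
  slope <- numeric(n)
  fc <- (band$f_low + band$f_high) / 2
  cyc <- max(2L, round(fs / fc))
  # the rotation ramp spans one cycle and completes half a cycle before the
  # event, so the signal in the immediate neighborhood of the reset latency
  # is a clean (constant) rotation of the analytic oscillator
  lead <- cyc %/% 2L
  ks <- round((resets$latency_s + band$reset_delay) * fs) + 1L
  total <- 0 # accumulated rotation from completed earlier ramps
  for (i in order(ks)) {
    k <- ks[i]
    if (k < 2L || k > n) next
    theta <- rvonmises(1, band$reset_phase, resets$kappa[i])
    delta <- wrap_angle(theta - wrap_angle(Arg(z[k]) + total))
    j1 <- max(1L, k - lead)
    j0 <- max(0L, j1 - cyc) # ramp spans samples (j0, j1]
    slope[(j0 + 1L):j1] <- slope[(j0 + 1L):j1] + delta / (j1 - j0)
    total <- total + delta
  }
  cumsum(slope)
}

#' Synthesize one participant's continuous multichannel recording
#'
#' Builds the composite signal specified by the configuration: per band a
#' noise-driven narrowband oscillator (order-4 zero-phase bandpass of white
#' noise) whose phase is redrawn from a von Mises distribution at each
#' resetting event and whose amplitude decays exponentially across delay
#' periods; category-specific narrowband spatial patterns injected while an
#' item is held in memory; 1/f background and white measurement noise per
#' channel; and a saturating spike artifact at each delivered TMS pulse.
#'
#' @param config a `synth_config`.
#' @param schedule schedule from [build_schedule()].
#' @param seed integer seed; output is deterministic given
#'   (config, schedule, seed).
#' @return list with elements `recording` (a `recording`) and `ground_truth`
#'   (list of true reset kappas/latencies, decay constants, and pattern
#'   amplitudes, one entry per simulated effect).
#' @export
synthesize_participant <- function(config, schedule, seed = config$seed) {
  validate_synth_config(config)
  fs <- config$fs
  dur <- attr(schedule, "total_duration")
  if (is.null(dur)) dur <- max(schedule$latency_s + schedule$duration_s) + 5
  n <- round(dur * fs)
  n2 <- next_fast_len(n)
  nch <- config$n_channels
  with_local_seed(seed, {
    data <- matrix(0, nrow = nch, ncol = n)
    tvec <- (seq_len(n) - 1) / fs
    gt_bands <- list()
    for (band in config$bands) {
      fc <- (band$f_low + band$f_high) / 2
      hbw <- band$rel_bandwidth * (band$f_high - band$f_low) / 2
      x <- narrowband_source(n2, fc - hbw, fc + hbw, fs)
      z <- analytic_signal(x)[seq_len(n)]
      resets <- band_reset_events(schedule, band)
      if (!is.null(resets) && nrow(resets) > 0) {
        rot <- apply_phase_resets(z, resets, band, fs, n)
        s <- Re(z * exp(1i * rot))
      } else {
        s <- Re(z)
      }
      if (is.finite(band$decay_tau)) {
        env <- rep(1, n)
        delays <- schedule[startsWith(schedule$event_label, "delay_"), ]
        for (j in seq_len(nrow(delays))) {
          i0 <- round(delays$latency_s[j] * fs) + 1L
          i1 <- min(n, round((delays$latency_s[j] + delays$duration_s[j]) * fs))
          if (i0 > n || i1 < i0) next
          env[i0:i1] <- exp(-(tvec[i0:i1] - delays$latency_s[j]) / band$decay_tau)
        }
        s <- s * env
      }
      # positive-mean spatial profile: oscillatory sources referenced against a
      # common electrode share sign across the montage
      g <- 1 + 0.5 * stats::rnorm(nch)
      w <- g / sqrt(sum(g^2)) * sqrt(nch)
      data <- data + (w * band$amplitude) %o% s
      gt_bands[[band$name]] <- list(
        kappa_by_event = band$reset_kappa,
        reset_window = c(band$reset_delay, band$reset_delay),
        reset_phase = band$reset_phase,
        decay_tau = band$decay_tau, amplitude = band$amplitude
      )
    }
    # category pattern injections during retention
    trials <- schedule_trials(schedule)
    sample_rows <- schedule[schedule$event_label == "sample", ]
    probe1 <- schedule[schedule$event_label == "probe1", ]
    probe2 <- schedule[schedule$event_label == "probe2", ]
    gt_patterns <- list()
    for (pat in config$patterns) {
      if (pat$effect_amplitude == 0) {
        gt_patterns[[pat$category]] <- list(band = pat$band, effect_amplitude = 0)
        next
      }
      bi <- which(vapply(config$bands, `[[`, "", "name") == pat$band)
      if (!length(bi)) stop_config("pattern band '%s' has no band_spec", pat$band)
      bs <- config$bands[[bi[1]]]
      q <- narrowband_source(n2, bs$f_low, bs$f_high, fs)[seq_len(n)]
      gate <- numeric(n)
      hold <- trials$trial[trials$category_cued == pat$category |
                             trials$category_uncued == pat$category]
      for (tr in hold) {
        t_on <- sample_rows$latency_s[sample_rows$trial == tr]
        p2 <- probe2$latency_s[probe2$trial == tr]
        t_off <- if (length(p2)) p2 + probe2$duration_s[probe2$trial == tr][1] else
          probe1$latency_s[probe1$trial == tr] + config$timing$probe
        i0 <- max(1L, round(t_on * fs) + 1L)
        i1 <- min(n, round(t_off * fs))
        if (i1 >= i0) gate[i0:i1] <- 1
      }
      w <- if (!is.null(pat$channel_weights)) pat$channel_weights else {
        g <- stats::rnorm(nch); g / sqrt(sum(g^2))
      }
      if (length(w) != nch) stop_config("pattern channel_weights: wrong length")
      data <- data + (w * sqrt(nch) * pat$effect_amplitude) %o% (q * gate)
      gt_patterns[[pat$category]] <- list(
        band = pat$band, effect_amplitude = pat$effect_amplitude
      )
    }
    # background noise
    if (config$pink_sd > 0) {
      for (ch in seq_len(nch)) {
        data[ch, ] <- data[ch, ] +
          config$pink_sd * pink_noise(n, config$noise_exponent, fs)
      }
    }
    if (config$white_sd > 0) {
      data <- data + matrix(stats::rnorm(nch * n, sd = config$white_sd),
                            nrow = nch)
    }
    # TMS pulse artifact: saturating spike spanning +/- 2 ms around the pulse
    pulses <- schedule[startsWith(schedule$event_label, "sptms"), ]
    if (nrow(pulses) > 0 && config$artifact_gain > 0) {
      sig_sd <- stats::sd(data[1L, seq(1L, n, by = max(1L, n %/% 20000L))])
      amp <- config$artifact_gain * sig_sd
      half <- round(0.002 * fs)
      for (j in seq_len(nrow(pulses))) {
        k <- round(pulses$latency_s[j] * fs) + 1L
        idx <- max(1L, k - half):min(n, k + half)
        data[, idx] <- amp
      }
    }
    rec <- recording(data, fs = fs,
                     channel_labels = sprintf("ch%02d", seq_len(nch)))
    list(recording = rec,
         ground_truth = list(bands = gt_bands, patterns = gt_patterns,
                             seed = seed))
  })
}
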