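#' Continuous multichannel recording
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels optional character vector of channel names.
#' @param start_time time of the first sample, seconds.
#' @return object of class `recording`.
#' @export
recording <- function(data, fs, channel_labels = NULL, start_time = 0) {
  data <- as.matrix(data)
  if (nrow(data) < 1L) stop_config("recording: need at least one channel")
  if (fs <= 0) stop_config("recording: fs must be > 0")
  if (anyNA(data)) stop_config("recording: missing samples are not allowed")
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 start_time = start_time),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Epoched trial data
#'
#' @param data numeric array trials x channels x time, microvolts.
#' @param time time axis in seconds relative to the lock event (t = 0).
#' @param fs sampling rate in Hz.
#' @param trial_meta data.frame with one row of attributes per trial.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, time, fs, trial_meta) {
  if (length(dim(data)) != 3L) stop_config("epoch_set: data must be 3-d")
  if (dim(data)[3] != length(time)) stop_config("epoch_set: time axis mismatch")
  if (nrow(trial_meta) != dim(data)[1]) {
    stop_config("epoch_set: trial_meta rows must equal n_trials")
  }
  structure(list(data = data, time = time, fs = fs, trial_meta = trial_meta),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoch_set: %d trials x %d channels x %d samples @ %g Hz, t in [%g, %g] s\n",
              d[1], d[2], d[3], x$fs, min(x$time), max(x$time)))
  invisible(x)
}

n_trials <- function(ep) dim(ep$data)[1]

#' Add dummy spTMS event tags to spTMS-absent delays
#'
#' Every eligible delay on which no pulse was delivered receives a
#' `dummy_sptms_*` tag at the lag (relative to cue offset) of the most recent
#' preceding spTMS-present delay of the same epoch type (Delay 1.2 or
#' Delay 2), so that absent trials pass through the identical epoching and
#' interpolation path. An absent delay with no preceding present delay falls
#' back to the median lag of the grid; if no present delay exists anywhere a
#' warning is raised and all dummies use that fallback.
#'
#' @param events event table as produced by [build_schedule()] (rows sorted
#'   by latency; delay rows carry `sptms_present` and `lag_s`).
#' @param fallback_lag lag used when no preceding present delay exists,
#'   seconds (default the 2-3 s grid median, 2.5 s).
#' @return the event table with dummy rows appended, re-sorted by latency.
#' @export
add_dummy_events <- function(events, fallback_lag = 2.5) {
  eligible <- events$event_label %in% c("delay_d12", "delay_d2")
  if (!any(eligible)) return(events)
  if (!any(events$sptms_present[eligible], na.rm = TRUE)) {
    warning("add_dummy_events: no spTMS-present delay exists; ",
            "all dummy tags use the fallback lag", call. = FALSE)
  }
  dummies <- NULL
  for (ep_type in c("delay_d12", "delay_d2")) {
    rows <- which(events$event_label == ep_type)
    if (!length(rows)) next
    rows <- rows[order(events$latency_s[rows])]
    last_lag <- NA_real_
    for (r in rows) {
      if (isTRUE(events$sptms_present[r])) {
        last_lag <- events$lag_s[r]
      } else {
        lag <- if (is.na(last_lag)) fallback_lag else last_lag
        d <- events[r, ]
        d$event_label <- sub("^delay_", "dummy_sptms_", d$event_label)
        d$latency_s <- d$latency_s + lag
        d$duration_s <- 0
        d$lag_s <- lag
        dummies <- rbind(dummies, d)
      }
    }
  }
  if (is.null(dummies)) return(events)
  out <- rbind(as.data.frame(events), dummies)
  out <- out[order(out$latency_s), ]
  rownames(out) <- NULL
  attributes_to_keep <- c("total_duration", "n_blocks")
  for (a in attributes_to_keep) attr(out, a) <- attr(events, a)
  class(out) <- class(events)
  out
}

#' Epoch a recording around matching events
#'
#' Extracts one trial per event whose label matches, mapping the sample at the
#' event latency to t = 0. Trials whose window extends beyond the recording
#' are dropped with a message reporting the count.
#'
#' @param rec a `recording`.
#' @param events event table.
#' @param label character vector of event labels to lock to.
#' @param window c(start, end) of the epoch relative to the event, seconds.
#' @return an `epoch_set`; `trial_meta` carries the matched event rows.
#' @export
epoch_around <- function(rec, events, label, window) {
  if (window[1] >= window[2]) stop_config("epoch_around: invalid window")
  sel <- events[events$event_label %in% label, , drop = FALSE]
  if (nrow(sel) == 0L) stop_config("epoch_around: no events with label %s",
                                   paste(label, collapse = "/"))
  fs <- rec$fs
  i0 <- round(window[1] * fs)
  i1 <- round(window[2] * fs)
  time <- (i0:i1) / fs
  n <- ncol(rec$data)
  lock <- round((sel$latency_s - rec$start_time) * fs) + 1L
  ok <- lock + i0 >= 1L & lock + i1 <= n
  if (any(!ok)) {
    message(sprintf("epoch_around: dropped %d/%d trials at recording boundary",
                    sum(!ok), length(ok)))
  }
  sel <- sel[ok, , drop = FALSE]
  if (nrow(sel) == 0L) stop_config("epoch_around: all trials fell outside the recording")
  lock <- lock[ok]
  nt <- length(time)
  nch <- nrow(rec$data)
  data <- array(0, dim = c(nrow(sel), nch, nt))
  for (j in seq_len(nrow(sel))) {
    data[j, , ] <- rec$data[, (lock[j] + i0):(lock[j] + i1)]
  }
  rownames(sel) <- NULL
  epoch_set(data, time, fs, as.data.frame(sel))
}

#' Interpolate the TMS pulse artifact gap
#'
#' Replaces samples in `span` (default -2 to 30 ms around the lock event) by a
#' least-squares cubic polynomial fitted to `context` seconds of data on each
#' side of the span, per trial and channel. Applied identically to pulse and
#' dummy-tagged trials.
#'
#' @param ep an `epoch_set` locked to the pulse (pulse at t = 0).
#' @param span c(start, end) of the replaced interval, seconds.
#' @param context context length fitted on each side, seconds.
#' @return the interpolated `epoch_set`.
#' @export
interpolate_pulse_gap <- function(ep, span = c(-0.002, 0.030), context = 0.005) {
  t <- ep$time
  if (span[1] < min(t) || span[2] > max(t)) {
    stop_config("interpolate_pulse_gap: span outside the epoch")
  }
  in_span <- t >= span[1] & t <= span[2]
  in_ctx <- (t >= span[1] - context & t < span[1]) |
    (t > span[2] & t <= span[2] + context)
  if (sum(in_ctx) < 4L) {
    stop_config("interpolate_pulse_gap: not enough context samples for a cubic fit")
  }
  # linear map from context samples to interpolated span samples
  X_ctx <- stats::poly(t[in_ctx], degree = 3, raw = TRUE)
  X_ctx <- cbind(1, X_ctx)
  X_span <- cbind(1, stats::poly(t[in_span], degree = 3, raw = TRUE))
  M <- X_span %*% solve(crossprod(X_ctx), t(X_ctx))
  d <- dim(ep$data)
  flat <- matrix(ep$data, nrow = d[1] * d[2], ncol = d[3])
  flat[, in_span] <- flat[, in_ctx] %*% t(M)
  ep$data <- array(flat, dim = d)
  ep
}

# zero-phase filter applied along the time axis of an epoch array
filtfilt_epochs <- function(ep, filt) {
  d <- dim(ep$data)
  flat <- matrix(ep$data, nrow = d[1] * d[2], ncol = d[3])
  for (r in seq_len(nrow(flat))) {
    flat[r, ] <- signal::filtfilt(filt, flat[r, ])
  }
  ep$data <- array(flat, dim = d)
  ep
}

#' Bandpass and notch filter an epoch set
#'
#' Zero-phase (forward-backward) order-4 Butterworth high- and low-pass
#' filters realizing the band, plus an order-2 Butterworth band-stop notch,
#' applied per channel and trial.
#'
#' @param ep an `epoch_set`.
#' @param band c(low, high) passband edges in Hz.
#' @param notch notch center frequency in Hz (half-width 2 Hz); NULL disables.
#' @return the filtered `epoch_set`.
#' @export
filter_band_notch <- function(ep, band = c(1, 100), notch = 60) {
  ny <- ep$fs / 2
  if (band[2] >= ny) stop_config("filter_band_notch: band exceeds Nyquist")
  hp <- signal::butter(4, band[1] / ny, type = "high")
  lp <- signal::butter(4, band[2] / ny, type = "low")
  ep <- filtfilt_epochs(ep, hp)
  ep <- filtfilt_epochs(ep, lp)
  if (!is.null(notch)) {
    if (notch + 2 >= ny) stop_config("filter_band_notch: notch exceeds Nyquist")
    bs <- signal::butter(2, c(notch - 2, notch + 2) / ny, type = "stop")
    ep <- filtfilt_epochs(ep, bs)
  }
  ep
}

#' Resample an epoch set
#'
#' Anti-aliased downsampling: an order-6 zero-phase Butterworth low-pass at
#' 80% of the target Nyquist frequency followed by cubic-spline evaluation on
#' the new time grid. The lock event stays at t = 0; upsampling is refused.
#'
#' @param ep an `epoch_set`.
#' @param target_fs new sampling rate, Hz (must be <= current fs).
#' @return the resampled `epoch_set`.
#' @export
resample_epochs <- function(ep, target_fs) {
  if (target_fs > ep$fs) stop_config("resample_epochs: upsampling not supported")
  if (target_fs == ep$fs) return(ep)
  lp <- signal::butter(6, 0.8 * target_fs / ep$fs, type = "low")
  ep <- filtfilt_epochs(ep, lp)
  t_new <- seq(ceiling(min(ep$time) * target_fs),
               floor(max(ep$time) * target_fs)) / target_fs
  d <- dim(ep$data)
  flat <- matrix(ep$data, nrow = d[1] * d[2], ncol = d[3])
  out <- matrix(0, nrow = nrow(flat), ncol = length(t_new))
  for (r in seq_len(nrow(flat))) {
    out[r, ] <- stats::spline(ep$time, flat[r, ], xout = t_new)$y
  }
  ep$data <- array(out, dim = c(d[1], d[2], length(t_new)))
  ep$time <- t_new
  ep$fs <- target_fs
  ep
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per trial and channel, the mean over the baseline window.
#'
#' @param ep an `epoch_set`.
#' @param baseline c(start, end) of the baseline window, seconds.
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(ep, baseline) {
  idx <- ep$time >= baseline[1] & ep$time <= baseline[2]
  if (!any(idx)) stop_config("baseline_correct: empty baseline window")
  mu <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - as.vector(mu) # recycles over the time axis
  ep
}

#' Average an epoch set across channels
#'
#' Unweighted mean over channels per trial and timepoint, yielding a
#' `trial_series` (trials x time) that feeds the phase and power analyses.
#'
#' @param ep an `epoch_set`.
#' @return object of class `trial_series` with fields data (trials x time
#'   matrix), time, fs, trial_meta.
#' @export
average_channels <- function(ep) {
  d <- dim(ep$data)
  data <- apply(ep$data, c(1, 3), mean)
  if (d[1] == 1L) data <- matrix(data, nrow = 1L)
  structure(list(data = data, time = ep$time, fs = ep$fs,
                 trial_meta = ep$trial_meta),
            class = "trial_series")
}

#' @export
print.trial_series <- function(x, ...) {
  cat(sprintf("trial_series: %d trials x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}
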