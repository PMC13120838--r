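#' Time-frequency power via Hanning-windowed convolution
#'
#' Power at integer frequencies 2-50 Hz from 500 ms Hanning-tapered segments
#' centered on a 500 ms grid locked to the epoch's t = 0. Centers whose
#' window would extend beyond the epoch are dropped. The per-frequency complex
#' coefficient is the tapered inner product with a complex exponential,
#' normalized so a unit-amplitude sinusoid at an analysis frequency yields
#' power 1.
#'
#' @param ep an `epoch_set`.
#' @param freqs integer analysis frequencies in Hz.
#' @param win_len analysis window length, seconds.
#' @param step spacing of window centers, seconds.
#' @return object of class `timefreq`: power array trials x channels x freqs
#'   x times, `freqs`, `times`, `fs`, `trial_meta`.
#' @export
spectral_transform <- function(ep, freqs = 2:50, win_len = 0.5, step = 0.5) {
  fs <- ep$fs
  L <- round(win_len * fs)
  if (L > length(ep$time)) stop_config("spectral_transform: epoch shorter than the window")
  half_lo <- floor((L - 1) / 2)
  half_hi <- L - 1 - half_lo
  t0 <- min(ep$time); t1 <- max(ep$time)
  centers <- seq(ceiling(t0 / step), floor(t1 / step)) * step
  keep <- logical(length(centers))
  cidx <- integer(length(centers))
  for (i in seq_along(centers)) {
    k <- round((centers[i] - t0) * fs) + 1L
    keep[i] <- (k - half_lo >= 1L) && (k + half_hi <= length(ep$time))
    cidx[i] <- k
  }
  centers <- centers[keep]; cidx <- cidx[keep]
  if (!length(centers)) stop_config("spectral_transform: no window fits the epoch")
  taper <- hann_taper(L)
  tseg <- (seq_len(L) - 1 - half_lo) / fs
  # complex carrier basis, tapered: L x n_freqs
  B <- exp(-2i * pi * outer(tseg, freqs)) * taper
  scale <- 2 / sum(taper) # unit-amplitude sinusoid -> |coef| = 1
  d <- dim(ep$data)
  flat <- matrix(ep$data, nrow = d[1] * d[2], ncol = d[3])
  pow <- array(0, dim = c(d[1], d[2], length(freqs), length(centers)))
  for (i in seq_along(centers)) {
    seg <- flat[, (cidx[i] - half_lo):(cidx[i] + half_hi), drop = FALSE]
    coef <- seg %*% B * scale
    pow[, , , i] <- array(Mod(coef)^2, dim = c(d[1], d[2], length(freqs)))
  }
  structure(list(power = pow, freqs = freqs, times = centers, fs = fs,
                 trial_meta = ep$trial_meta),
            class = "timefreq")
}

#' @export
print.timefreq <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("timefreq: %d trials x %d channels x %d freqs x %d times\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Log-transform and temporally smooth a time-frequency object
#'
#' log10 of power (floored at machine epsilon) followed by a centered 3-point
#' moving average along the time axis, so each 500 ms timepoint aggregates
#' 1.5 s of data; endpoints average their available neighbors.
#'
#' @param tf a `timefreq`.
#' @return the transformed `timefreq` (power now log10 units).
#' @export
log_and_smooth <- function(tf) {
  p <- log10(pmax(tf$power, .Machine$double.eps))
  nt <- dim(p)[4]
  if (nt == 1L) { tf$power <- p; return(tf) }
  acc <- p
  cnt <- array(1, dim(p))
  acc[, , , 1:(nt - 1)] <- acc[, , , 1:(nt - 1), drop = FALSE] +
    p[, , , 2:nt, drop = FALSE]
  cnt[, , , 1:(nt - 1)] <- cnt[, , , 1:(nt - 1), drop = FALSE] + 1
  acc[, , , 2:nt] <- acc[, , , 2:nt, drop = FALSE] + p[, , , 1:(nt - 1), drop = FALSE]
  cnt[, , , 2:nt] <- cnt[, , , 2:nt, drop = FALSE] + 1
  tf$power <- acc / cnt
  tf
}

#' Average a time-frequency object within frequency bands
#'
#' Unweighted mean over the integer frequencies belonging to each band under
#' the half-open edge convention (f_low, f_high], lowest band closed at f_low.
#'
#' @param tf a `timefreq`.
#' @param bands list of `band_def` (see [default_band_defs()]).
#' @return list of `timefreq` objects, one per band, each with a single
#'   (averaged) frequency dimension.
#' @export
band_average <- function(tf, bands = default_band_defs("broadband")) {
  out <- list()
  for (b in bands) {
    bins <- band_bins(b, tf$freqs)
    if (!length(bins)) stop_config("band_average: band '%s' has no bins", b$name)
    idx <- match(bins, tf$freqs)
    bp <- apply(tf$power[, , idx, , drop = FALSE], c(1, 2, 4), mean)
    tfb <- tf
    tfb$power <- array(bp, dim = c(dim(tf$power)[1], dim(tf$power)[2], 1,
                                   dim(tf$power)[4]))
    tfb$freqs <- mean(bins)
    tfb$band <- b$name
    out[[b$name]] <- tfb
  }
  out
}

#' Assemble a decoding feature set at one timepoint
#'
#' Rows are trials, features are channel x band power values at the requested
#' grid timepoint, and the binary label is whether `category` is part of the
#' trial's memory array (cued or uncued item). In broadband mode all bands
#' contribute (60 channels x 3 bands = 180 features under the default
#' montage); in single-band mode one band contributes (60 features).
#'
#' @param band_tf list of per-band `timefreq` from [band_average()].
#' @param timepoint analysis timepoint, seconds (must lie on the grid).
#' @param category category whose presence/absence is decoded.
#' @param mode "broadband" (all bands) or the name of a single band.
#' @return list of class `feature_set`: X (samples x features), y (0/1),
#'   feature_names, condition.
#' @export
assemble_features <- function(band_tf, timepoint, category,
                              mode = "broadband") {
  tf1 <- band_tf[[1]]
  ti <- which(abs(tf1$times - timepoint) < 1e-9)
  if (!length(ti)) stop_config("assemble_features: timepoint %g off the grid", timepoint)
  use <- if (identical(mode, "broadband")) names(band_tf) else mode
  if (!all(use %in% names(band_tf))) {
    stop_config("assemble_features: unknown band in mode '%s'", mode)
  }
  X <- NULL; fn <- NULL
  for (b in use) {
    tfb <- band_tf[[b]]
    Xb <- tfb$power[, , 1, ti]
    if (is.null(dim(Xb))) Xb <- matrix(Xb, nrow = dim(tfb$power)[1])
    X <- cbind(X, Xb)
    fn <- c(fn, sprintf("%s_ch%02d", b, seq_len(ncol(Xb))))
  }
  meta <- tf1$trial_meta
  y <- as.integer(meta$category_cued == category |
                    meta$category_uncued == category)
  if (min(table(factor(y, levels = 0:1))) < 2L) {
    stop_config("assemble_features: need at least 2 samples per class")
  }
  structure(list(X = X, y = y, feature_names = fn,
                 condition = list(category = category, mode = mode,
                                  timepoint = timepoint)),
            class = "feature_set")
}
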