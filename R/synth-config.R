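#' Band oscillator specification for the synthetic generator
#'
#' Describes one narrowband oscillatory component of the simulated EEG: its
#' frequency band, amplitude, which events reset its phase and how strongly
#' (von Mises concentration kappa per event label), an optional latency of the
#' reset relative to the event, and an optional exponential amplitude decay
#' across delay periods.
#'
#' @param name band label (theta, alpha, low_beta, high_beta).
#' @param f_low,f_high band edges in Hz.
#' @param amplitude oscillation amplitude in microvolts (SD of the band
#'   component).
#' @param reset_kappa named list/vector mapping event labels (e.g. "cue1",
#'   "sptms") to von Mises concentrations >= 0. Events absent from the map do
#'   not reset this band.
#' @param reset_delay latency of the phase reset after the event, seconds.
#' @param reset_phase target mean phase of the reset, radians.
#' @param decay_tau exponential amplitude decay time constant across delay
#'   periods, seconds; `Inf` disables decay.
#' @param rel_bandwidth bandwidth of the noise-driven oscillator as a
#'   fraction of the nominal band width, centered on the band midpoint. The
#'   default 0.5 gives a clearly narrowband rhythm whose phase diffuses over
#'   a few cycles rather than within one, as empirical EEG rhythms do.
#' @return object of class `band_spec`.
#' @export
band_spec <- function(name, f_low, f_high, amplitude = 1,
                      reset_kappa = list(), reset_delay = 0,
                      reset_phase = 0, decay_tau = Inf,
                      rel_bandwidth = 0.5) {
  if (f_low >= f_high) stop_config("band_spec: need f_low < f_high")
  if (amplitude < 0) stop_config("band_spec: amplitude must be >= 0")
  kap <- unlist(reset_kappa)
  if (length(kap) && any(kap < 0)) {
    stop_config("band_spec: von Mises kappa must be >= 0")
  }
  if (decay_tau <= 0) stop_config("band_spec: decay_tau must be > 0")
  if (rel_bandwidth <= 0 || rel_bandwidth > 1) {
    stop_config("band_spec: rel_bandwidth must lie in (0, 1]")
  }
  structure(list(name = name, f_low = f_low, f_high = f_high,
                 amplitude = amplitude, reset_kappa = as.list(reset_kappa),
                 reset_delay = reset_delay, reset_phase = reset_phase,
                 decay_tau = decay_tau, rel_bandwidth = rel_bandwidth),
            class = "band_spec")
}

default_band_specs <- function() {
  list(
    band_spec("theta", 4, 8, amplitude = 1.2,
              reset_kappa = list(cue1 = 1, cue2 = 1, sptms = 2),
              decay_tau = 8),
    band_spec("alpha", 8, 13, amplitude = 1.5,
              reset_kappa = list(cue1 = 1, cue2 = 1, sptms = 2),
              decay_tau = 6),
    band_spec("low_beta", 13, 20, amplitude = 0.8,
              reset_kappa = list(cue1 = 2, cue2 = 2, sptms = 4),
              decay_tau = 5),
    band_spec("high_beta", 20, 30, amplitude = 0.5,
              reset_kappa = list(sptms = 4),
              decay_tau = 4)
  )
}

#' Category-specific spatial band-power pattern
#'
#' Gives the linear decoder something to find: while a category is held in the
#' memory array, a narrowband source in `band` is injected with a fixed
#' spatial profile `channel_weights` (unit Euclidean norm) scaled by
#' `effect_amplitude`. Weights left NULL are drawn once per participant from a
#' seeded standard normal and normalized.
#'
#' @param category one of "face", "word", "motion".
#' @param band band label of an existing `band_spec`.
#' @param effect_amplitude injection amplitude in microvolts; 0 disables.
#' @param channel_weights optional length-n_channels numeric vector.
#' @return object of class `category_pattern`.
#' @export
category_pattern <- function(category, band, effect_amplitude = 1,
                             channel_weights = NULL) {
  if (effect_amplitude < 0) stop_config("category_pattern: negative amplitude")
  structure(list(category = category, band = band,
                 effect_amplitude = effect_amplitude,
                 channel_weights = channel_weights),
            class = "category_pattern")
}

default_category_patterns <- function(effect_amplitude = 1) {
  list(category_pattern("face", "alpha", effect_amplitude),
       category_pattern("word", "low_beta", effect_amplitude),
       category_pattern("motion", "high_beta", effect_amplitude))
}

#' Synthetic-experiment configuration
#'
#' Bundles every parameter of the simulated DSR/SR experiment: the trial and
#' block structure, trial-phase timing, spTMS scheduling, the band oscillators
#' and category patterns, and the background-noise model. The defaults follow
#' the emulated study: 60 channels at 1450 Hz, three sessions of eight
#' 30-trial blocks alternating DSR and SR, spTMS on 50% of delays at lags of
#' 2-3 s after cue offset in 50 ms steps.
#'
#' @param n_participants number of simulated participants.
#' @param n_trials_per_block trials per block.
#' @param n_blocks blocks per session.
#' @param n_sessions sessions per participant.
#' @param n_channels EEG channels.
#' @param fs sampling rate, Hz.
#' @param bands list of `band_spec`.
#' @param patterns list of `category_pattern`.
#' @param noise_exponent 1/f^a background-noise slope a.
#' @param pink_sd SD of the 1/f background per channel, microvolts.
#' @param white_sd SD of the white measurement noise per channel, microvolts.
#' @param timing named list of trial-phase durations in seconds: sample,
#'   delay11, cue, delay12, probe, response, and `iti_range` (length 2).
#' @param sptms_prob probability of spTMS in each eligible delay.
#' @param sptms_lag_grid admissible lags (s) of the pulse after cue offset.
#' @param artifact_gain TMS artifact amplitude as a multiple of the composite
#'   signal SD (spike spanning +/- 2 ms around the pulse).
#' @param seed integer seed controlling all randomness downstream.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_participants = 12,
                         n_trials_per_block = 30,
                         n_blocks = 8,
                         n_sessions = 3,
                         n_channels = 60,
                         fs = 1450,
                         bands = default_band_specs(),
                         patterns = default_category_patterns(),
                         noise_exponent = 1,
                         pink_sd = 1,
                         white_sd = 0.5,
                         timing = list(sample = 2, delay11 = 5, cue = 0.5,
                                       delay12 = 4.5, probe = 1, response = 2,
                                       iti_range = c(2, 4)),
                         sptms_prob = 0.5,
                         sptms_lag_grid = seq(2, 3, by = 0.05),
                         artifact_gain = 100,
                         seed = 1L) {
  cfg <- structure(list(
    n_participants = n_participants, n_trials_per_block = n_trials_per_block,
    n_blocks = n_blocks, n_sessions = n_sessions, n_channels = n_channels,
    fs = fs, bands = bands, patterns = patterns,
    noise_exponent = noise_exponent, pink_sd = pink_sd, white_sd = white_sd,
    timing = timing, sptms_prob = sptms_prob,
    sptms_lag_grid = sptms_lag_grid, artifact_gain = artifact_gain,
    seed = as.integer(seed)
  ), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  counts <- c(cfg$n_participants, cfg$n_trials_per_block, cfg$n_blocks,
              cfg$n_sessions, cfg$n_channels)
  if (any(counts < 1)) stop_config("synth_config: counts must be positive")
  if (cfg$fs <= 0) stop_config("synth_config: fs must be > 0")
  if (cfg$sptms_prob < 0 || cfg$sptms_prob > 1) {
    stop_config("synth_config: sptms_prob must lie in [0, 1]")
  }
  need <- c("sample", "delay11", "cue", "delay12", "probe", "response")
  dur <- unlist(cfg$timing[need])
  if (length(dur) != length(need) || any(dur <= 0)) {
    stop_config("synth_config: trial-phase durations must all be > 0")
  }
  if (any(cfg$timing$iti_range <= 0) || diff(cfg$timing$iti_range) < 0) {
    stop_config("synth_config: invalid iti_range")
  }
  if (length(cfg$sptms_lag_grid) < 1 || any(cfg$sptms_lag_grid < 0)) {
    stop_config("synth_config: invalid sptms_lag_grid")
  }
  if (max(cfg$sptms_lag_grid) >= cfg$timing$delay12) {
    stop_config("synth_config: spTMS lags must fall inside Delay 1.2")
  }
  if (length(cfg$bands) == 0) stop_config("synth_config: bands must be non-empty")
  for (b in cfg$bands) {
    if (b$f_high >= cfg$fs / 2) {
      stop_config("synth_config: band '%s' exceeds the Nyquist frequency", b$name)
    }
  }
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "synth_config: %d participants, %d sessions x %d blocks x %d trials, %d ch @ %g Hz\n",
    x$n_participants, x$n_sessions, x$n_blocks, x$n_trials_per_block,
    x$n_channels, x$fs))
  cat(sprintf("  bands: %s\n",
              paste(vapply(x$bands, `[[`, "", "name"), collapse = ", ")))
  cat(sprintf("  spTMS: p = %g, lags %g-%g s (%d values)\n",
              x$sptms_prob, min(x$sptms_lag_grid), max(x$sptms_lag_grid),
              length(x$sptms_lag_grid)))
  invisible(x)
}
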