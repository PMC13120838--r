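# Shared reduced-scale fixtures. Trial-phase durations are shortened outside
# the delay of interest so the synthetic recordings stay small; the delay,
# pulse-lag grid and counterbalancing follow the package defaults.

tiny_timing <- function() {
  list(sample = 0.5, delay11 = 0.5, cue = 0.5, delay12 = 4.5, probe = 0.5,
       response = 0.5, iti_range = c(1, 1.5))
}

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_participants = 1, n_trials_per_block = 8, n_blocks = 2, n_sessions = 1,
    n_channels = 4, fs = 250, timing = tiny_timing(),
    white_sd = 0.2, pink_sd = 0.4
  )
  do.call(synth_config, utils::modifyList(defaults, args))
}

# single-trial epoch_set built directly from a matrix (channels x time)
epochs_from_matrix <- function(mat, fs, t0 = 0, time = NULL) {
  nt <- ncol(mat)
  if (is.null(time)) time <- t0 + (seq_len(nt) - 1) / fs
  data <- array(mat, dim = c(1, nrow(mat), nt))
  epoch_set(data, time = time, fs = fs,
            trial_meta = data.frame(trial = 1))
}

# multi-trial single-channel epoch_set from a trials x time matrix
epochs_from_trials <- function(trials, fs, time) {
  data <- array(trials, dim = c(nrow(trials), 1, ncol(trials)))
  epoch_set(data, time = time, fs = fs,
            trial_meta = data.frame(trial = seq_len(nrow(trials))))
}

trial_series_from_matrix <- function(trials, fs, time) {
  structure(list(data = trials, time = time, fs = fs,
                 trial_meta = data.frame(trial = seq_len(nrow(trials)))),
            class = "trial_series")
}

phase_set_from_matrix <- function(phase, fs = 100, band = "alpha",
                                  time = NULL) {
  if (is.null(time)) time <- (seq_len(ncol(phase)) - 1) / fs - 2
  structure(list(phase = phase, time = time, fs = fs, band = band,
                 trial_meta = data.frame(trial = seq_len(nrow(phase)))),
            class = "phase_set")
}
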