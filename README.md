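# wmpulse

Tools for studying how single-pulse TMS (spTMS), delivered during the delay
of a retrocued visual working-memory task, perturbs the EEG: does the pulse
restore the decodability of memory items held at different priority levels,
and does it reorganize the phase and power of ongoing oscillations? The
package is aimed at cognitive electrophysiologists who want a tested,
reusable implementation of this analysis chain — and, because participant
recordings from such experiments are not redistributable, it is driven
end-to-end by a synthetic-EEG generator with known ground truth, so every
stage can be validated against the parameters that produced its input.

## What it implements

**Synthetic generator** (`synth_config()`, `build_schedule()`,
`synthesize_participant()`): the double-serial-retrocue (DSR) and
single-retrocue (SR) trial structure with counterbalanced categories and
spTMS scheduling (50% of delays, lags 2–3 s after cue offset in 50 ms
steps), and a 60-channel 1450 Hz signal model — narrowband noise-driven
oscillators per frequency band, event-locked von Mises phase resets of
concentration κ, exponential delay-period amplitude decay, category-specific
spatial band-power patterns, 1/f plus white noise, and a saturating ±2 ms
pulse artifact. Ground truth is returned alongside the recording.

**Preprocessing** (`add_dummy_events()`, `epoch_around()`,
`interpolate_pulse_gap()`, `filter_band_notch()`, `resample_epochs()`,
`baseline_correct()`, `average_channels()`): dummy spTMS tags on
pulse-absent delays, pulse-locked epoching, cubic artifact-gap interpolation
(−2 to 30 ms), zero-phase 1–100 Hz bandpass with 60 Hz notch, anti-aliased
resampling, ITI baseline correction and channel averaging.

**Decoding** (`spectral_transform()`, `log_and_smooth()`, `band_average()`,
`assemble_features()`, `fit_eval_auc()`, `aggregate_group()`): 500 ms
Hanning-window power at integer 2–50 Hz on a 500 ms grid, log10 + 3-point
temporal smoothing, band averages (theta/alpha/beta, with beta split for
band-specific decoding), and presence/absence classification by L2 logistic
regression (λ = 1, unpenalized intercept, imbalance bias correction) under
stratified five-fold cross-validation with nested z-scoring, random
pair-averaging of samples and 10 repetitions, summarized as AUC with
category medians per participant.

**Inference** (`cluster_perm_vs_chance()`, `cluster_perm_paired()`,
`compare_epochs_wilcoxon()`, `paired_permutation()`, `rayleigh_test()`,
`fdr_bh()`, `wilcoxon_signed_rank()`, `rank_biserial()`,
`required_sample_size()`): cluster-based permutation tests on AUC curves,
paired permutation tests for phase/power measures, Rayleigh tests of
circular clustering with FDR correction, exact signed-rank tests with
rank-biserial effect sizes, and noncentral-t power analysis.

**Phase dynamics** (`instantaneous_phase()`, `plv_timecourse()`,
`select_window()`, `wp_plv_change()`, `mean_phase_shift()`,
`intersubject_plv()`, `normalize_vs_absent()`,
`time_resolved_consistency()`): Butterworth + Hilbert instantaneous phase at
100 Hz and three complementary measures of event-related phase
reorganization —

- within-participant PLV change: post-minus-pre across-trial phase-locking
  value, `PLV(t) = |n⁻¹ Σ exp(iφ)|`;
- mean phase-angle shift: circular mean over trials of the post−pre circular
  mean phase difference;
- intersubject PLV: resultant length of participant shifts, with bootstrap
  SE —

computed in a data-driven analysis window: integer-cycle candidate windows
(2–4 cycles for theta/alpha, 3–6 for beta) slide in 10 ms steps over the
post-event period (30–500 ms for pulses) and the window maximizing the
absolute group t statistic of the post−pre PLV difference is selected. For a
von Mises reset of concentration κ the expected PLV is the Bessel ratio
I₁(κ)/I₀(κ) (`expected_plv()`), which anchors the validation.

**Power dynamics** (`relative_band_power()`, `pre_post_power_test()`,
`between_condition_power_test()`): Hanning-tapered 1 s FFT spectra and each
band's share of total 1–45 Hz power, with permutation tests for pre/post and
spTMS-present/absent contrasts.

**Pipeline** (`simulate_dataset()`, `analyze_dataset()`,
`report_dataset()`; thin CLI at `inst/cli/wmpulse.R`): dataset simulation to
disk (float32 + JSON sidecar recordings, TSV events, JSON ground truth), the
full analysis with TSV result tables and a run manifest, and a markdown
report.

## Worked example

Simulate four participants whose low-beta (13–20 Hz) oscillation undergoes a
κ = 4 phase reset 150 ms after each pulse, then let the adaptive window
search find the effect and quantify it:

```r
library(wmpulse)

cfg <- synth_config(
  n_participants = 4, n_trials_per_block = 24, n_blocks = 1, n_sessions = 1,
  n_channels = 8, fs = 500,
  bands = list(band_spec("low_beta", 13, 20, amplitude = 1,
                         reset_kappa = list(sptms = 4), reset_delay = 0.15)),
  patterns = list(),
  timing = list(sample = 0.5, delay11 = 0.5, cue = 0.5, delay12 = 4.5,
                probe = 0.5, response = 0.5, iti_range = c(1, 1.5)),
  white_sd = 0.3, pink_sd = 0.6)

low_beta <- band_def("low_beta", 13, 20)
phase_sets <- lapply(1:4, function(p) {
  sched <- build_schedule(cfg, seed = p)
  syn <- synthesize_participant(cfg, sched, seed = 100 + p)
  ep <- epoch_around(syn$recording, sched, "sptms_d12", c(-2, 2))
  ep <- interpolate_pulse_gap(ep)
  ep <- resample_epochs(ep, 100)
  instantaneous_phase(average_channels(ep), low_beta)
})

(w <- select_window(phase_sets, low_beta, "sptms"))
#> window_spec: low_beta/sptms, 3 cycles, onset 100 ms, length 180 ms (t = 7.55)

m <- compute_phase_measures(phase_sets, w, seed = 1)
round(m$wp_plv_change, 3)
#> [1] 0.478 0.639 0.349 0.635
round(m$mean_shift * 180 / pi, 1)
#> [1]  61.6  39.5  47.7  -5.2
round(m$intersubject$r, 3)
#> [1] 0.908
```

The search lands on a 100–280 ms window — covering the simulated 150 ms
reset — with a group selection statistic of t = 7.55. All four participants
show substantial post-event increases in across-trial phase locking
(0.35–0.64; a κ = 4 reset has asymptotic PLV `expected_plv(4)` = 0.864
against a low pre-event baseline), and their mean phase shifts align across
participants (intersubject PLV r = 0.91, bootstrap SE 0.05). On
pulse-absent trials the same window shows no such change, and
`normalize_vs_absent()` expresses the measures relative to that baseline.

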