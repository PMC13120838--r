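---
title: "Simulating and analyzing spTMS effects on working-memory EEG: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing spTMS effects on working-memory EEG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmpulse)
```

wmpulse studies how a single pulse of transcranial magnetic stimulation
(spTMS), delivered during the delay of a retrocued working-memory task,
reorganizes the phase and power of ongoing EEG oscillations and restores the
decodability of memory items held at different priority levels. Because no
participant-level recordings from such experiments are redistributable, the
package is built around a synthetic-EEG generator with known ground truth:
every analysis stage can therefore be validated against the parameters that
produced its input, and the statistical machinery can be calibrated against
exchangeable nulls. This vignette explains the signal model, the analysis
chain, the tunable parameters, and the numerical choices; it also states
plainly what the synthetic validation does and does not establish about real
data.

## The experiment being emulated

Two tasks share a common first half. In the single-retrocue (SR) task,
participants memorize two sample items drawn from two of three categories
(face, word, dot-motion direction), a spatial cue then indicates which item
will be tested, and a recognition probe follows a 4.5 s delay ("Delay 1.2").
The double-serial-retrocue (DSR) task continues after the first probe with a
second cue and a second delay ("Delay 2") and probe. The item not selected by
the first DSR cue remains potentially relevant — an unprioritized memory item
(UMI) — whereas the uncued SR item and the item uncued by the second DSR cue
are irrelevant (IMI). On half of all eligible delays a TMS pulse is delivered
2–3 s after cue offset, at a lag drawn from a uniform 50 ms grid; with
independent 50% scheduling in the two DSR delays, a quarter of DSR trials
receive two pulses. `build_schedule()` reproduces this structure with exact
counterbalancing whenever block trial counts divide evenly, and
`synth_config()` carries the trial-phase durations (2 s sample, 5 s
Delay 1.1, 0.5 s cue, 4.5 s delays, 1 s probes, 2 s response windows,
2–4 s inter-trial intervals), 60 channels, and the 1450 Hz acquisition rate
as defaults.

## The signal model

Each participant's continuous recording is the sum of

1. **Band oscillators.** One per frequency band (theta 4–8, alpha 8–13, low
   beta 13–20, high beta 20–30 Hz): white noise bandpass-filtered (order-4
   zero-phase Butterworth) into a passband centered on the band midpoint,
   scaled to the band's amplitude, and mixed into the montage through a fixed
   per-participant spatial profile. The oscillator's inner bandwidth is a
   fraction `rel_bandwidth` of the nominal band width (default 0.5). This
   parameter exists because a narrowband process's phase decorrelates on a
   timescale of roughly the inverse bandwidth: an oscillator occupying the
   full 5 Hz alpha band loses phase memory within a single cycle, so even a
   perfectly concentrated reset is measured (through any causal-width filter)
   far below its nominal phase-locking value. At `rel_bandwidth = 0.5` the
   rhythm drifts over a few cycles — consistent with the sustained appearance
   of empirical alpha — and measured PLV at a reset tracks the analytic value
   closely. Setting `rel_bandwidth = 1` recovers a fast-diffusing rhythm,
   which the window-selection validation uses when it needs a phase
   perturbation genuinely confined in time.
2. **Phase resets.** At each resetting event (configurable per band; e.g.
   cues and pulses), a target phase is drawn from a von Mises distribution
   with concentration kappa about the band's target phase. The analytic
   representation of the oscillator is rotated so that its phase at the event
   latency equals the drawn value exactly, with the rotation ramped in
   linearly over one cycle, completing half a cycle before the event. The
   ramp avoids any amplitude discontinuity (rotation preserves the envelope
   identically, so power statistics cannot be confounded by the reset
   mechanism), and finishing it before the latency keeps the neighborhood of
   the measurement point free of pre-reset phase leakage. Across trials the
   phases at the event are therefore exact von Mises draws, and the expected
   across-trial PLV is the Bessel ratio I1(kappa)/I0(kappa), exposed as
   `expected_plv()` and used as the recovery oracle.
3. **Amplitude dynamics.** A band with finite `decay_tau` decays
   exponentially from each delay onset, emulating the decline of oscillatory
   power across memory delays; the envelope restarts at every delay.
4. **Category patterns.** While a category is part of the trial's memory
   array, a dedicated narrowband source in that category's band is injected
   through a fixed unit-norm random spatial pattern scaled by
   `effect_amplitude` (microvolts; 0 disables). This is what a linear decoder
   can exploit; it is an artifact construct — the emulated study does not
   claim any particular per-category EEG signature.
5. **Noise.** Per-channel 1/f background (spectral exponent 1 by default,
   SD `pink_sd`) plus white measurement noise (`white_sd`).
6. **Pulse artifact.** Each delivered pulse saturates all channels for
   ±2 ms at `artifact_gain` (default 100) times the signal SD, so the
   interpolation stage has genuine work to do.

The band-oscillator spatial profiles are drawn once per participant as
`1 + 0.5 N(0,1)` and normalized: a positive-mean topography, reflecting that
rhythms referenced against a common electrode share sign across a montage.
A zero-mean profile would make the channel-averaged series — the substrate of
all phase and power analyses — nearly cancel the oscillators it is supposed
to carry.

## Preprocessing

The shipped order follows standard TMS-EEG practice: dummy-event tagging,
epoching, downsampling to 500 Hz, pulse-gap interpolation, broadband
filtering; the phase/power path additionally baseline-corrects, downsamples
to 100 Hz, and averages across channels.

- **Dummy tags** (`add_dummy_events()`): every spTMS-absent eligible delay
  receives a tag at the lag of the most recent preceding spTMS-present delay
  of the same epoch type, so absent trials traverse the identical epoching
  and interpolation path. A first trial with no predecessor uses the grid
  median (2.5 s); a schedule with no pulses anywhere warns and uses the
  fallback throughout.
- **Gap interpolation** (`interpolate_pulse_gap()`): samples from −2 to
  +30 ms around the pulse are replaced by a least-squares cubic fitted to
  5 ms of context on each side (more context can be requested at low
  sampling rates, where 5 ms holds too few samples for a cubic). A
  least-squares fit was preferred over an exact 4-point interpolant for
  robustness to single-sample noise.
- **Filtering** (`filter_band_notch()`): order-4 zero-phase Butterworth
  high- and low-pass (1–100 Hz) plus an order-2 band-stop notch (60 ± 2 Hz),
  realized as cascaded sections rather than a single narrow bandpass for
  numerical stability at a 0.004 normalized low edge.
- **Resampling** (`resample_epochs()`): order-6 zero-phase Butterworth
  anti-alias low-pass at 80% of the target Nyquist, then cubic-spline
  evaluation on the new grid; the lock sample stays at t = 0 and upsampling
  is refused. Epochs whose window exceeds the recording are dropped with a
  logged count (the boundary policy is drop-and-log).

## Time–frequency features and decoding

`spectral_transform()` computes power at integer frequencies 2–50 Hz from
500 ms Hanning-tapered segments centered on a 500 ms grid; windows that do
not fit the epoch are dropped, not zero-padded. Power is log10-transformed
(floored at machine epsilon, for synthetic silence) and smoothed with a
centered 3-point moving average, so each timepoint aggregates 1.5 s;
endpoints average their available neighbors. Note the frequency resolution of
a 500 ms window is 2 Hz: a sinusoid at an odd integer frequency lands between
bins, and its mainlobe spans ±2 Hz (81% of its 2–50 Hz power in the ±1 Hz
bins, 98% within ±2 Hz). Band averages use half-open membership
(f_low, f_high], with the lowest band (theta) closed at 4 Hz — the convention
that resolves edge frequencies printed as belonging to two adjacent bands.
Broadband decoding stacks theta/alpha/beta(13–30) channel averages
(60 × 3 = 180 features under the default montage); band-specific decoding
uses a single band's 60 channels, with beta split into low (13–20) and high
(20–30).

`fit_eval_auc()` implements the classification protocol: per repetition,
samples are shuffled and averaged in random within-class pairs (odd
remainders discarded), split into stratified five folds, z-scored per fold
using training-fold statistics only, and scored by an L2-penalized logistic
regression (penalty 0.5·lambda·||w||² with lambda = 1 on the weights only)
fit by IRLS in the row space of the design (exact for a pure L2 penalty, and
fast when features outnumber samples). Class imbalance is handled by
balanced-loss weighting with a subsequent intercept shift of log(n1/n0) —
one concrete reading of a "bias correction", which cannot affect AUC (a
rank statistic) but keeps predicted probabilities centered. The AUC is
averaged over 5 folds × 10 repetitions; per participant the median across
the three categories is taken before group averaging.

Group inference uses cluster-based permutation: timepoint-wise one-sample t
statistics (against AUC 0.5, or on paired condition differences), clusters as
contiguous supra-threshold runs of consistent sign with a two-tailed
alpha = 0.05 cluster-forming threshold, cluster mass as summed t, and a
max-mass null from per-participant sign flips (default 5000 permutations;
both threshold and count are field-conventional choices, as the emulated
analysis does not state them). Cluster p values include the observed value
in the null set ((1 + count)/(1 + n_perm)), which is mildly conservative but
valid. Between-epoch comparisons at single timepoints use one-tailed
Wilcoxon signed-rank tests with the matched-pairs rank-biserial correlation
rbc = 2W/(n(n+1)/2) − 1 as effect size.

## Phase analyses

Phase is always computed at 100 Hz on channel-averaged, baseline-corrected
4 s epochs centered on the event: order-4 zero-phase Butterworth bandpass
into the target band, analytic signal by the Hilbert transform, phase as its
argument.

Because the latency at which a band responds to an event is not known a
priori, the analysis window is selected by a frequency-adaptive sliding
search (`select_window()`): candidate lengths are integer numbers of
oscillatory cycles (2–4 for theta/alpha, 3–6 for the betas), converted to
time by the band midpoint frequency (6, 10.5, 16.5, 25 Hz) and rounded down
to the 10 ms sample grid; onsets slide in 10 ms steps over the post-event
period (from 0 for cues, from 30 ms for pulses — past the interpolated gap —
up to 500 ms, with the window allowed to extend past 500 ms up to the epoch
end). For each candidate, every participant contributes post-minus-pre PLV
against an equal-length pre-event window ending at the event; the candidate
maximizing the absolute group t statistic wins, with deterministic
tie-breaking (earliest onset, then fewest cycles). Selection pools all data
of the event class, and the window selected on spTMS-present trials is
reused for the absent trials.

Three measures are computed in the selected window, per condition:

- **Within-participant PLV change** — mean across-trial PLV over the post
  window minus the pre window.
- **Mean phase-angle shift** — per trial, the circular difference between
  post- and pre-window circular mean phases; the participant value is the
  circular mean of trial shifts. (The window-mean-then-difference reading
  was chosen over differencing matched timepoints; both are defensible.)
  The resultant length of the trial shifts is kept as a confidence
  diagnostic, flagged below 0.1 — a participant whose trial shifts are
  uniform has no meaningful direction.
- **Intersubject PLV** — resultant length of the participant shifts, with a
  1000-resample participant bootstrap SE.

spTMS measures are normalized against the dummy-tagged absent trials
(arithmetic subtraction for PLV change, circular difference for shifts).
Between-condition inference uses a paired permutation test (5000 iterations,
per-participant label flips, two-tailed p as twice the smaller inclusive
tail proportion, floored at 1/n_iter), FDR-corrected across bands. The
time-resolved consistency analysis evaluates ten 50 ms windows with onsets
50–500 ms post-event: per window, participants' mean phase angles are tested
for clustering with the Rayleigh test (finite-n approximation
p = exp(√(1+4n+4(n²−R²)) − (1+2n))), and present/absent differences in
resultant length by a 1000-iteration label-swap permutation, each
FDR-corrected over the ten windows.

All circular computations are wrap-equivariant (angles live in (−π, π]),
and PLV-type measures are invariant under global phase rotation; both
properties are asserted numerically in the test suite.

## Power analyses

`relative_band_power()` takes the 1 s segment before or after the event,
applies a Hanning taper, computes the FFT power spectrum at 1 Hz resolution,
and reports the band's share of total 1–45 Hz power — a ratio immune to
overall amplitude scaling. Band membership follows the same half-open
convention as the decoding features. Pre/post contrasts use per-trial
label-flip permutation; present/absent contrasts pool the trials and permute
labels preserving group sizes (implemented within participant; pooling
across participants before permuting would be the alternative reading). No
detrending is applied beyond the pipeline's baseline correction.

## Supporting statistics

The Wilcoxon signed-rank implementation drops zero differences, uses the
exact sign-flip null for n ≤ 25 without ties and a tie- and
continuity-corrected normal approximation otherwise. Required-sample-size
computations evaluate power directly from the noncentral t distribution
(ncp = d√n), iterating n upward; a large-sample normal approximation
⌈((z_{1−α}+z_{power})/d)²⌉ is also exposed because the two methods
genuinely disagree for moderate effects (at d = 0.8, α = 0.05, power = 0.8
one-tailed, the noncentral-t answer is 12 while the normal approximation
gives 10), and which one a given power calculator reports is not always
discoverable. Benjamini–Hochberg adjustment delegates to the standard
step-up implementation behind a validated interface.

## Validation scale and what it shows

The shipped validation (test suite and `scripts/acceptance.R`) runs at desk
scale, chosen once: phase-recovery experiments use one participant × 200
pulse trials at 250 Hz with 4 channels and shortened non-delay trial phases
(the 4.5 s delay, the 2–3 s lag grid and the counterbalancing are kept);
window-recovery uses 50 datasets of 6 participants × 20 trials;
inferential calibration uses 1000–1500 exchangeable null datasets at 1000
permutations; decoding uses ~120-sample feature sets with 180 features. At
these sizes the full suite completes in minutes. Measured outcomes: PLV at a
reset tracks I1(κ)/I0(κ) within Monte-Carlo error for κ ∈ {0, 1, 4}; the
selected window midpoint falls inside a truly confined 100–300 ms reset in
≈96% of datasets; paired-permutation, Rayleigh and cluster tests reject at
4–5% under their nulls; the decoder sits at chance under label shuffling and
saturates for 3×noise-SD injections.

Passing these checks shows the machinery is implemented correctly and
calibrated — it does not show that real EEG satisfies the generator's
assumptions. The generator omits, deliberately: ocular/muscle artifacts and
their ICA cleanup, electrode drift and bad channels, volume-conduction
head-model structure, cross-band coupling, and any veridical mapping from
stimulus categories to scalp patterns. Results on synthetic data therefore
validate the pipeline, not the neuroscience; group-level findings from the
emulated study (which depend on unavailable participant data) are out of
scope by construction.

## Reproducibility

Every stochastic operation takes an explicit seed and restores the caller's
RNG state; identical (configuration, seed) pairs give bit-identical
schedules, recordings and result tables. Derived per-stage seeds stay within
32-bit integer range. Permutation p values are never reported as zero (floor
1/n_iter), and all serialized outputs are plain text (TSV/JSON) apart from
the float32 recording payload, which carries a JSON sidecar describing its
layout.
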