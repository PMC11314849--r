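---
title: "Detecting motor imagery with few electrodes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting motor imagery with few electrodes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A wearable EEG device for detecting imagined movements must work with very
few electrodes and modest computation. `mieeg` implements and compares two
detection pipelines built for that setting, together with the synthetic data,
preprocessing, classification harness and sweep machinery needed to study
their design trade-offs (electrode sets, trial counts, component counts,
reduced-dimension parameters, sampling rates) end to end on a desk.

Both detectors work from *epochs*: fixed-length windows cut at event onsets
and labeled with a movement class (five fingers) or rest.

## The synthetic generator

`synthetic_spec()` / `generate_recording()` produce labeled multi-channel
recordings whose class structure is event-related desynchronization (ERD):
during imagined movement, the sensorimotor mu rhythm over the contralateral
motor cortex loses band power.

The model, per channel:

* background noise: Gaussian white noise filtered (zero-phase) to the
  recording passband and rescaled so the delivered noise has standard
  deviation `noise_sd`. No 1/f shape, no ocular or muscle artifacts.
* on motor channels (defaults C3, C4): a mu-band oscillation at the center
  of `erd_band_hz` (default 8-12 Hz) with rest-state band power
  `osc_amplitude^2 / 2`. Its amplitude envelope is a smooth burst train
  (`sin^6` at `osc_burst_hz`, normalized to unit RMS): sensorimotor rhythms
  wax and wane rather than holding constant amplitude, and the bursting
  makes the rhythm super-Gaussian, which is what makes it *extractable* by a
  negentropy-seeking decomposition. During movement-class epochs the
  oscillation's amplitude is multiplied by `sqrt(1 - erd_depth)`, so its
  band power drops by exactly `erd_depth`.
* optionally a mains sinusoid (50/60 Hz) on every channel.

Defaults emulate the structure of a five-finger, 22-channel, 1 kHz recording
with a 0.53-100 Hz passband, 1 s movement epochs and 1.5-2.5 s rest epochs
(drawn uniformly per event; the sources state a range, not a value). Event
order is randomized per seed so block order cannot leak into
cross-validation. 160 Hz and 9.524 kHz regimes are reached through
`sampling_rate_hz`.

**A deliberate simplification.** The oscillation's phase (and burst
envelope) is locked to each epoch onset, for every class. Real ERD is
*induced* - the rhythm is not phase-locked to events, and trial-averaged
waveforms cancel. We lock the phase so that the mean across trials (the
template the correlation detector uses) retains the rhythm; with an induced
rhythm, template correlations carry almost no class information and only the
band-power detector would have signal. Consequences: passing end-to-end
tests here demonstrates the pipelines' mechanics and their sensitivity to
band-power structure, **not** performance on real induced-ERD recordings.
The band-power (FB-CSSP) results are insensitive to this choice; the
correlation-feature results depend on it.

Amplitudes are arbitrary units throughout; the emulated recordings publish
no amplitude scale.

## Preprocessing

* `remove_line_artifact()`: a second-order (biquad) notch at 50/60 Hz,
  applied forward-backward (zero-phase). Quality factor defaults to 45: with
  the double pass, Q = 45 attenuates the line by far more than 30 dB while
  altering frequencies more than 2 Hz away by under 1 dB; a lower Q cannot
  meet both bounds once the response is squared by the double pass.
* All bandpass steps are fourth-order Butterworth designs (order-2 analog
  prototype, 4 poles) run through `signal::filtfilt`, so epochs are never
  delayed (an impulse's peak stays put). This design is numerically stable
  in double precision down to the 0.5-4 Hz band at 9.524 kHz; cascading
  separate high/low-pass biquads was rejected because their -3 dB corners
  compound and sag narrow 4 Hz bands by several dB at band center.
* `epoch_recording()` cuts half-open windows `[onset, onset + len)` with
  1-based onsets - the R convention, applied uniformly. Rest epochs, longer
  at the source, are cropped to the analysis window so every trial row has
  equal length. Epochs overrunning the record are dropped and counted.
* `assemble_trial_matrix()` stacks trials electrode-major (all trials of
  electrode 1, then electrode 2, ...): with 4 trials of 2000 samples and two
  electrodes the matrix is 8 x 2000.
* `make_reference_row()` draws the seeded standard-Gaussian "random signal"
  appended to every trial matrix, so the decomposition is never biased
  toward a predefined waveform. Gaussian white noise is the maximal-entropy
  choice for an uninformative reference.

## The FastICACorr detector

`fastica_extract()` is a deflationary fixed-point independent component
analysis maximizing non-Gaussianity via the negentropy approximation. Rows
of the observation matrix (trials x electrodes, plus the reference row) are
centered and whitened by the eigendecomposition of their covariance; each
component direction `w` then iterates

    w <- E[ z g(w'z) ] - E[ g'(w'z) ] w

in whitened space, Gram-Schmidt-orthogonalized against accepted components
and renormalized, until the direction change falls below `tol` (default
1e-4, `max_iter` 200). The three classic contrast functions are available:
log-cosh (a = 1, default), the Gaussian kernel, and the quartic (kurtosis)
contrast.

Two robustness choices matter at these problem sizes (about 21 rows and
1000 serially-correlated samples):

* **Restart pool with projection pursuit.** Each deflation step runs
  `restarts` (default 5) seeded Gaussian starts and keeps the converged
  direction with the largest negentropy proxy `|E G(w'z) - E G(nu)|`. A
  single random start in 21 dimensions frequently converges to a spurious
  finite-sample extremum; because deflation removes whatever was accepted,
  the genuine source then gets smeared over later components. The restart
  pool makes the strongest source come out first and intact.
* Components that never converge are flagged, not fatal; the iteration cap
  per attempt stays at `max_iter`.

`corr_features()` reduces each component to one Pearson (r, p) pair against
the extraction input. The input is a multi-row matrix while a component is
one row, so a template stands in for the input; this is an interpretation,
and both readings are implemented:

* `template = "mean"`: the mean across trial rows - a single 1 x samples
  vector.
* `template = "per_trial"`: correlate each trial row with the component and
  average the r values (p recomputed from the averaged r).

`pearson_r_p()` computes the textbook coefficient and its two-sided
significance from `t = r sqrt((N-2)/(1-r^2))` on `N - 2` degrees of freedom
(`p = 0` at `|r| = 1`); it is checked against a definitional sum-formula
oracle and `stats::cor.test`.

### Observation units for classification

`build_fastica_feature_dataset()` supports two units:

* `unit = "pair"` (default): each (r, p) pair is one labeled 2-feature
  observation - n observations per extraction.
* `unit = "run"`: the n pairs of one extraction form one observation:
  `absr_k` (|r| sorted descending; ICA component order and sign are
  arbitrary) and `nlp_k` (-log10 p, matched order).

The benchmarks and sweeps use `unit = "run"` with
`template = "per_trial"`. The reasons are geometric. Pearson r is invariant
to scale, and ERD is a scale effect, so a mean-template correlation sees the
rhythm's suppression only through the template's signal-to-noise fraction -
a thin margin that a single (r, p) pair cannot resolve; pairs from one
extraction are also statistically dependent, which breaks the observation
independence cross-validation assumes. Per-trial-row correlations, by
contrast, estimate the *per-row* SNR of the rhythm component
(about sqrt(P/(P + sigma^2))), are sign-consistent across rows for an
onset-locked rhythm, and degrade gracefully when the rhythm splits across
components. Significance values are compared on the log scale, where their
class difference is visible to a margin classifier.

## The FB-CSSP detector

`build_filter_bank()` constructs the fixed plan: delta 0.5-4, theta 4-8,
alpha 8-12 Hz; sub-beta 12-16, 16-20, 20-24, 24-28, 28-32; sub-gamma 30-34,
34-38, 38-42, 42-46 (the 28-32 / 30-34 overlap is part of the printed plan
and kept); then unknown 5 Hz tiles from 55 or 65 Hz (choose 55 with
50 Hz-mains data, 65 with 60 Hz-mains data) up to the data's frequency
limit, the final tile truncated. Band edges are half-open for the tiling
arithmetic; the filters use the printed corner frequencies. The feature
harness defaults the limit to `min(100, Nyquist)`: 100 Hz is the passband
of the kHz-rate recordings emulated here, and tiling noise-only bands
beyond the data's bandwidth only dilutes the classifier.

`cssp_fit()` solves the two-class common-spatial-pattern problem over the
band-stacked representation: trace-normalized covariances `C_A`, `C_B`
(normalizing per trial before averaging is the classic CSP convention),
simultaneous diagonalization of `(C_A, C_A + C_B)` via whitening of the
composite, eigenvalues in `[0, 1]` sorted descending, and `2m` spatial
filters - the `m` most A-favoring plus the `m` most B-favoring directions
(`m` is the reduced-dimension parameter; only two classes can be compared at
once). A ridge (default 1e-9 of the trace) handles singular composites.

`cssp_features()` emits the paired vectors `f_a` and `f_b`, one entry per
band: the per-band log-variance profile under the fitted projection
(`log(sum_j W_jk^2 * var_k)`), with `f_b` computed under the model fitted
with the class roles inverted. With multiple electrodes, each electrode's
band outputs are stacked (rows = electrodes x bands).

`build_cssp_feature_dataset()` is fold-aware: trials are assigned to
stratified folds first, the comparator is fitted on training trials only,
and every trial's profile is computed under that fold's projection - no
test-trial information reaches the model. Per-run and per-trial readings of
`f_a`/`f_b` are both defensible; the per-trial reading is implemented
because a classifier cannot be trained from one vector per run.

`crossval_evaluate_cssp()` defaults to the Gaussian naive-Bayes
discriminant (diagonal class-conditional covariances). With ~36 training
trials against ~21 log-variance bands, a margin maximizer (SVM) tilts into
whichever noise bands spuriously separate the training folds and gives away
5-10 points of test accuracy; a diagonal discriminant weights each band by
its own evidence and is the standard choice for spatial-pattern
log-variance features. The SVM remains available everywhere
(`classifier_id = "svm"`).

## Classification harness

`crossval_evaluate()` runs stratified k-fold cross-validation (k = 10 by
default; stratification keeps small per-class counts from producing
degenerate folds), trains per fold on the training split only, and pools
predictions into a success rate (percent correct) and a row-normalized
confusion matrix. Everything is deterministic given the seed. The SVM is
libsvm via `e1071` (one-vs-one voting for more than two classes); any other
model can plug in through a `list(train =, predict =)` contract.

## Experiments

`experiment_config()` / `run_experiment()` sweep the Cartesian grid of
electrode sets x trial counts x detector parameter x class comparisons for
three regimes: pooled movement vs rest, each movement vs rest, and all
pairwise comparisons (15 for six classes) plus a multi-class confusion
matrix. Electrode labels are validated against the 10-20 montage vocabulary
(C3, Cz, C4, P3, Pz, P4, F3, Fz, F4, F7, F8, T5, T6, ...), with a
hemisphere tag available for handedness questions. Failed cells are
recorded and the sweep continues; identical (config, seed) reproduces the
report exactly. `time_components()` reports wall-clock seconds per
extracted component - reported only, never asserted, because timing is
hardware-dependent.

## Problem sizes and numerical choices

The shipped analyses and tests run at the emulated study conditions
(22 channels, 1 kHz, 20 trials per class, 20 components, electrode C4,
10-fold CV) with 20 feature repetitions per class; sweeps in
`analysis/05_sweeps.R` use 10 repetitions over three electrode sets. These
sizes complete in minutes on one core while leaving the statistics stable.

Numerical notes: whitening rejects eigenvalues at or below 1e-12 of the
largest (naming the deficient dimension - duplicated trial rows are the
usual cause); ICA convergence is `1 - |<w_new, w>| < 1e-4`; CSSP
eigenvalues are clamped to `[0, 1]` against rounding; `p = 0` is declared
only at exactly `|r| = 1`; feature tables floor p at 1e-300 before taking
logs. Rest epochs with only `n_trials` available are "resampled" as seeded
permutations (the subset cannot vary, only the order and the reference row
do) - with 20 rest trials the run-level observations for the rest class are
therefore more similar to one another than independent draws would be,
which the permutation-null checks guard against.

## Known limitations

* No forward-modeled scalp topographies, no ocular/muscle artifacts, no
  between-subject variability beyond the seed; the generator's realism ends
  at band-limited noise plus a burst-modulated, onset-locked rhythm.
* The EDF adapter is read-only and minimal (16-bit EDF, no annotations).
* Multiclass spatial-pattern extensions (one-vs-one trees) are out of
  scope; the comparator is strictly two-class.
* Success rates on this synthetic benchmark say nothing quantitative about
  the external recordings the structure emulates; they validate mechanics,
  contracts, and relative behavior (component counts, electrode additions,
  parameter sweeps).
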