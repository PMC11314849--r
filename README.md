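# mieeg — motor-imagery EEG detection pipelines

Detecting *imagined* movements from EEG with very few electrodes is the core
problem of wearable brain–computer interfaces: the device must decide, from
one or two scalp channels over motor cortex, whether the wearer is imagining
a movement (and which one) — with algorithms simple enough to run on the
device. `mieeg` implements two complete detection pipelines for this setting
and the machinery to study their design trade-offs end to end:

* **FastICACorr** — deflationary FastICA over a stacked trial matrix
  augmented with a random reference row, followed by one Pearson (r, p)
  feature pair per extracted component. The one-unit fixed point maximizes
  the negentropy approximation

      w ← E[ z g(wᵀz) ] − E[ g′(wᵀz) ] w

  in whitened space (contrasts: log cosh, Gaussian, quartic), with
  Gram–Schmidt deflation and a seeded restart pool per component.
* **FB-CSSP** — a fixed filter bank (delta/theta/alpha, five sub-beta and
  four sub-gamma 4-Hz bands, then 5-Hz "unknown" tiles up to the data's
  frequency limit) feeding a two-class common-spatial-pattern comparator of
  reduced dimension *m*: trace-normalized band covariances C_A, C_B,
  simultaneous diagonalization of (C_A, C_A + C_B), and paired per-band
  log-variance profiles f_a, f_b.

Around the detectors: a seeded synthetic generator of event-related
desynchronization (ERD) EEG (movement epochs lose mu-band power on motor
channels), mains-notch and zero-phase bandpass preprocessing, epoching and
trial-matrix assembly, a stratified 10-fold cross-validated classification
harness (SVM and naive-Bayes discriminants, plus a plug-in contract), sweep
drivers over electrode sets / trial counts / component counts / *m*, and
per-component timing reports. A minimal EDF reader/writer is included for
interoperability.

## Worked example

The numbered scripts under `analysis/` run the whole study desk-scale.
`analysis/01_simulate.R` simulates a 22-channel, 1 kHz five-finger recording
(ERD depth 0.6 on C3/C4, 20 trials per class, 50 Hz mains) and notches the
mains; `02`/`03` extract features for movement-vs-rest on electrode C4;
`04` classifies them. Condensed:

```r
library(mieeg)

spec <- synthetic_spec(trials_per_class = 20, erd_depth = 0.6, seed = 2024)
rec  <- generate_recording(spec)
ep   <- pool_movement_classes(epoch_recording(rec, 1))

feats <- build_fastica_feature_dataset(
  ep, "C4", c("movement", "rest"), n_components = 20, n_trials = 20,
  repetitions = 20, unit = "run", template = "per_trial", seed = 101)
cols <- grep("^(absr|nlp)_", names(feats), value = TRUE)
crossval_evaluate(feats[, cols], feats$class_label, k_folds = 10,
                  seed = 301, kernel = "linear")
```

Running the scripts prints:

```
FastICACorr movement vs rest: 100.0%
label-permutation null: 50.8%
FB-CSSP movement vs rest: 100.0%
mean alpha-band log-variance by class: movement -0.57, rest 0.26
mean top-profile correlation by class: movement 0.518, rest 0.58
```

Reading the numbers: both detectors separate imagined movement from rest
perfectly on this synthetic benchmark, and permuting the labels collapses
the success rate to chance (~50%), so the separation is real, not leakage.
The alpha-band log-variance gap (−0.57 vs 0.26, a power ratio of ≈ 0.43) is
the injected ERD itself — the rhythm's band power drops by the configured 60%
during imagined movement — and the correlation profiles show the rest-state
rhythm correlating more strongly with its independent component than the
suppressed movement-state rhythm does.

`analysis/05_sweeps.R` reproduces the design-decision sweeps (electrode sets
× component counts for FastICACorr; electrode sets × *m* for FB-CSSP) and
writes the per-component timing table.

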