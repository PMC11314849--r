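Package: mieeg
Title: Motor-Imagery EEG Detection Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting imagined (motor-imagery) movements in
    multi-channel EEG with very few electrodes. Implements two detection
    pipelines: FastICACorr, which runs deflationary FastICA over a stacked
    trial matrix augmented with a random reference row and summarises each
    independent component by its Pearson (r, p) correlation with the trial
    template; and FB-CSSP, which decomposes each trial through a fixed
    delta/theta/alpha/sub-beta/sub-gamma plus 5-Hz-tile filter bank and fits a
    two-class common-spatial-pattern comparator of reduced dimension m over
    the band stack. Includes a seeded synthetic generator of event-related
    desynchronization (ERD) EEG, mains-notch and bandpass preprocessing,
    epoching, a stratified cross-validated SVM classification harness, and
    experiment sweeps over electrode sets, trial counts, component counts and
    sampling rates, together with per-component timing reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
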