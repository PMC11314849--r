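#' Remove a mains-line artifact with a zero-phase notch
#'
#' A second-order (biquad) notch centered on the mains frequency, applied
#' forward-backward so epoch timing is not delayed. With the default quality
#' factor the mains component is attenuated far beyond 30 dB while frequencies
#' more than 2 Hz away are altered by less than 1 dB.
#'
#' @param recording an `mi_recording`.
#' @param mains_hz mains frequency, 50 or 60; must be below Nyquist.
#' @param q notch quality factor (center frequency / -3 dB width, single pass).
#' @return the filtered recording.
#' @export
remove_line_artifact <- function(recording, mains_hz, q = 45) {
  if (!inherits(recording, "mi_recording")) stop("`recording` must be an mi_recording")
  if (!mains_hz %in% c(50, 60)) stop("`mains_hz` must be 50 or 60")
  fs <- recording$sampling_rate_hz
  if (mains_hz >= fs / 2) {
    stop("mains frequency ", mains_hz, " Hz is at or above Nyquist (",
         fs / 2, " Hz)")
  }
  co <- notch_coefficients(mains_hz, fs, q)
  filt <- signal::Arma(b = co$b, a = co$a)
  out <- recording
  for (i in seq_len(nrow(out$data))) {
    out$data[i, ] <- signal::filtfilt(filt, out$data[i, ])
  }
  out
}

# RBJ-cookbook biquad notch coefficients.
notch_coefficients <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Cut a recording into labeled epochs
#'
#' One epoch per event, aligned to the event onset, with half-open sample
#' window `[onset, onset + round(window_s * fs))` (1-based onsets). Events
#' whose window overruns the end of the recording are dropped and the count is
#' reported with a message.
#'
#' @param recording an `mi_recording` with events.
#' @param window_s epoch window in seconds (> 0).
#' @return an `mi_epochs` object: list of epochs (`data` channels x samples,
#'   `class_label`, `onset_sample`), plus `sampling_rate_hz`,
#'   `channel_labels`, `epoch_length_samples`.
#' @export
epoch_recording <- function(recording, window_s) {
  if (!inherits(recording, "mi_recording")) stop("`recording` must be an mi_recording")
  if (window_s <= 0) stop("`window_s` must be positive")
  if (nrow(recording$events) == 0) stop("recording has no events to epoch")
  len <- as.integer(round(window_s * recording$sampling_rate_hz))
  ev <- recording$events
  fits <- ev$onset_sample + len - 1L <= ncol(recording$data)
  if (any(!fits)) {
    message(sum(!fits), " epoch(s) overran the recording and were dropped")
  }
  ev <- ev[fits, , drop = FALSE]
  epochs <- lapply(seq_len(nrow(ev)), function(i) {
    idx <- ev$onset_sample[i]:(ev$onset_sample[i] + len - 1L)
    list(data = recording$data[, idx, drop = FALSE],
         class_label = ev$class_label[i],
         onset_sample = ev$onset_sample[i])
  })
  structure(list(epochs = epochs,
                 sampling_rate_hz = recording$sampling_rate_hz,
                 channel_labels = recording$channel_labels,
                 epoch_length_samples = len),
            class = "mi_epochs")
}

#' @export
print.mi_epochs <- function(x, ...) {
  tab <- table(vapply(x$epochs, `[[`, "", "class_label"))
  cat(sprintf("<mi_epochs> %d epochs x %d samples @ %g Hz [%s]\n",
              length(x$epochs), x$epoch_length_samples, x$sampling_rate_hz,
              paste(names(tab), tab, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Pool all movement classes of an epoch set under one label
#'
#' Relabels every non-rest epoch as `"movement"`, for general-movement-vs-rest
#' comparisons.
#'
#' @param epochs an `mi_epochs` object.
#' @param pooled_label label given to non-rest epochs.
#' @return the relabeled `mi_epochs`.
#' @export
pool_movement_classes <- function(epochs, pooled_label = "movement") {
  stopifnot(inherits(epochs, "mi_epochs"))
  epochs$epochs <- lapply(epochs$epochs, function(e) {
    if (e$class_label != "rest") e$class_label <- pooled_label
    e
  })
  epochs
}

#' Assemble the stacked trial matrix for one class
#'
#' Rows are ordered electrode-major: all trials of the first electrode, then
#' all trials of the second, and so on. With 4 trials and one electrode of
#' 2000-sample epochs the result is 4 x 2000; with two electrodes, 8 x 2000.
#'
#' @param epochs an `mi_epochs` object.
#' @param electrode_labels electrodes to stack, in order.
#' @param class_label class whose trials are stacked.
#' @param n_trials optional number of trials to use (the first `n_trials`
#'   matching epochs in input order); `NULL` uses all.
#' @return an `mi_trial_matrix`: list with `rows`
#'   ((trials x electrodes) x samples matrix), `electrode_labels`,
#'   `trials_per_electrode`, `class_label`, `sampling_rate_hz`.
#' @export
assemble_trial_matrix <- function(epochs, electrode_labels, class_label,
                                  n_trials = NULL) {
  stopifnot(inherits(epochs, "mi_epochs"))
  unknown <- setdiff(electrode_labels, epochs$channel_labels)
  if (length(unknown)) {
    stop("unknown electrode(s): ", paste(unknown, collapse = ", "))
  }
  sel <- Filter(function(e) e$class_label == class_label, epochs$epochs)
  if (length(sel) == 0) stop("no trials for class '", class_label, "'")
  if (!is.null(n_trials)) {
    if (length(sel) < n_trials) {
      stop(n_trials, " trials requested for class '", class_label,
           "' but only ", length(sel), " available")
    }
    sel <- sel[seq_len(n_trials)]
  }
  rows <- do.call(rbind, lapply(electrode_labels, function(el) {
    do.call(rbind, lapply(sel, function(e) e$data[el, ]))
  }))
  rownames(rows) <- paste0(rep(electrode_labels, each = length(sel)),
                           "_t", rep(seq_along(sel), length(electrode_labels)))
  structure(list(rows = rows,
                 electrode_labels = electrode_labels,
                 trials_per_electrode = length(sel),
                 class_label = class_label,
                 sampling_rate_hz = epochs$sampling_rate_hz),
            class = "mi_trial_matrix")
}

#' Seeded random reference row
#'
#' Standard Gaussian white-noise row appended to the trial matrix so the
#' independent-component extraction is not biased toward any predefined
#' signal. Same seed, same vector.
#'
#' @param n_samples length of the row (> 0).
#' @param seed integer seed.
#' @return an `mi_reference_row`: list with `samples` and `seed`.
#' @export
make_reference_row <- function(n_samples, seed) {
  if (n_samples <= 0) stop("`n_samples` must be positive")
  samples <- with_seed(seed, rnorm(n_samples))
  structure(list(samples = samples, seed = as.integer(seed)),
            class = "mi_reference_row")
}
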