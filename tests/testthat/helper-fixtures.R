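# Small, fast synthetic configurations used across the unit tests.

small_spec <- function(...) {
  args <- list(...)
  defaults <- list(
    sampling_rate_hz = 250,
    n_channels = 6,
    channel_labels = c("C3", "Cz", "C4", "P3", "Pz", "P4"),
    classes = c("thumb", "rest"),
    trials_per_class = 8,
    movement_epoch_s = 1,
    rest_epoch_s_range = c(1.2, 1.6),
    erd_band_hz = c(8, 12),
    erd_depth = 0.5,
    noise_sd = 1,
    passband_hz = c(0.53, 45),
    seed = 42L
  )
  do.call(synthetic_spec, utils::modifyList(defaults, args))
}

# A bare recording around a given matrix (bypasses the generator).
matrix_recording <- function(data, fs, labels = paste0("ch", seq_len(nrow(data))),
                             events = NULL) {
  if (is.null(events)) {
    events <- data.frame(onset_sample = integer(), class_label = character(),
                         n_samples = integer(), stringsAsFactors = FALSE)
  }
  rownames(data) <- labels
  structure(list(data = data, sampling_rate_hz = fs, channel_labels = labels,
                 events = events),
            class = "mi_recording")
}

# Periodogram band power, independent of the package's filtering helpers.
band_power <- function(x, fs, lo, hi) {
  s <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                         plot = FALSE, detrend = TRUE)
  2 * sum(s$spec[s$freq >= lo & s$freq <= hi]) * (s$freq[2] - s$freq[1])
}

rms <- function(x) sqrt(mean(x^2))

# Epoch subset helper preserving the mi_epochs structure.
epochs_subset <- function(epochs, idx) {
  epochs$epochs <- epochs$epochs[idx]
  epochs
}
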