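#' Specification of a synthetic motor-imagery EEG recording
#'
#' Describes a labeled multi-channel EEG-like recording with class-dependent
#' band-power structure. The defaults emulate the structure of a 5-finger
#' motor-imagery recording: 22 channels at 1 kHz inside a 0.53-100 Hz
#' passband, ~1 s movement epochs, 1.5-2.5 s rest epochs, six classes (five
#' fingers plus rest). 160 Hz and 9.524 kHz regimes are obtained by changing
#' `sampling_rate_hz` (and, if wanted, the epoch lengths).
#'
#' During movement-class epochs the narrow-band oscillation carried by
#' `motor_channels` is attenuated multiplicatively so that its band power
#' drops by the fraction `erd_depth` relative to rest epochs - the
#' event-related desynchronization (ERD) the detectors must find. The
#' oscillation is phase-locked to each epoch onset (see the methods vignette
#' for what that simplification does and does not emulate).
#'
#' @param sampling_rate_hz sampling rate in Hz.
#' @param n_channels number of channels; must equal `length(channel_labels)`.
#' @param channel_labels 10-20-system channel names, unique.
#' @param classes ordered subset of
#'   `c("thumb","index","middle","ring","pinkie","rest")`.
#' @param trials_per_class events generated per class.
#' @param movement_epoch_s duration of each movement-class epoch, seconds.
#' @param rest_epoch_s_range length-2 `(lo, hi)`; each rest epoch's duration is
#'   drawn uniformly from this range.
#' @param erd_band_hz length-2 band `(lo, hi)` of the class-modulated
#'   oscillation; must lie inside `(0, sampling_rate_hz/2)`.
#' @param erd_depth fraction in `[0, 1)` by which the oscillation's band power
#'   drops during movement epochs on `motor_channels`.
#' @param osc_amplitude rest-state RMS amplitude of the oscillation (arbitrary
#'   units; the emulated recordings state no amplitude scale). The rest-state
#'   band power contributed by the oscillation is `osc_amplitude^2 / 2`.
#' @param osc_burst_hz burst rate of the oscillation's amplitude envelope in
#'   Hz. Sensorimotor rhythms wax and wane rather than running at constant
#'   amplitude; the envelope is a smooth onset-locked burst train
#'   (`sin^6`, unit RMS), making the rhythm super-Gaussian as real rhythm
#'   bursts are. Set to 0 for a constant-amplitude sinusoid.
#' @param motor_channels subset of `channel_labels` carrying the oscillation.
#' @param noise_sd standard deviation of the delivered (band-limited)
#'   background Gaussian noise on every channel.
#' @param line_freq_hz optional mains frequency, 50 or 60 (NULL for none).
#' @param line_amplitude amplitude of the mains sinusoid added to every
#'   channel when `line_freq_hz` is set.
#' @param passband_hz length-2 passband `(lo, hi)` applied (zero-phase) to the
#'   background noise.
#' @param seed integer seed; identical spec + seed give identical recordings.
#' @return an object of class `mi_synthetic_spec`.
#' @export
synthetic_spec <- function(sampling_rate_hz = 1000,
                           n_channels = 22,
                           channel_labels = default_channel_labels(n_channels),
                           classes = c("thumb", "index", "middle", "ring",
                                       "pinkie", "rest"),
                           trials_per_class = 20,
                           movement_epoch_s = 1,
                           rest_epoch_s_range = c(1.5, 2.5),
                           erd_band_hz = c(8, 12),
                           erd_depth = 0.6,
                           osc_amplitude = 2,
                           osc_burst_hz = 1,
                           motor_channels = intersect(c("C3", "C4"), channel_labels),
                           noise_sd = 1,
                           line_freq_hz = NULL,
                           line_amplitude = 0,
                           passband_hz = c(0.53, 100),
                           seed = 1L) {
  allowed <- c("thumb", "index", "middle", "ring", "pinkie", "rest")
  if (length(classes) == 0) stop("`classes` must be nonempty")
  if (anyDuplicated(classes)) stop("duplicate class labels rejected")
  if (!all(classes %in% allowed)) {
    stop("`classes` must be a subset of {", paste(allowed, collapse = ", "), "}")
  }
  if (sampling_rate_hz <= 0) stop("`sampling_rate_hz` must be positive")
  if (n_channels < 1) stop("`n_channels` must be a positive integer")
  if (length(channel_labels) != n_channels) {
    stop("`channel_labels` must have length `n_channels`")
  }
  if (anyDuplicated(channel_labels)) stop("duplicate channel labels rejected")
  if (trials_per_class < 1) stop("`trials_per_class` must be positive")
  if (movement_epoch_s <= 0) stop("`movement_epoch_s` must be positive")
  if (length(rest_epoch_s_range) != 2 || any(rest_epoch_s_range <= 0) ||
      rest_epoch_s_range[1] > rest_epoch_s_range[2]) {
    stop("`rest_epoch_s_range` must be positive with lo <= hi")
  }
  if (length(erd_band_hz) != 2 || erd_band_hz[1] <= 0 ||
      erd_band_hz[2] >= sampling_rate_hz / 2 || erd_band_hz[1] >= erd_band_hz[2]) {
    stop("`erd_band_hz` must lie within (0, sampling_rate_hz/2)")
  }
  if (erd_depth < 0 || erd_depth >= 1) stop("`erd_depth` must be in [0, 1)")
  if (!all(motor_channels %in% channel_labels)) {
    stop("`motor_channels` must be a subset of `channel_labels`")
  }
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  if (!is.null(line_freq_hz)) {
    if (!line_freq_hz %in% c(50, 60)) stop("`line_freq_hz` must be 50 or 60")
    if (line_amplitude < 0) stop("`line_amplitude` must be nonnegative")
  }
  if (length(passband_hz) != 2 || passband_hz[1] < 0 ||
      passband_hz[1] >= passband_hz[2]) {
    stop("`passband_hz` must be an increasing pair")
  }
  structure(list(
    sampling_rate_hz = sampling_rate_hz,
    n_channels = as.integer(n_channels),
    channel_labels = channel_labels,
    classes = classes,
    trials_per_class = as.integer(trials_per_class),
    movement_epoch_s = movement_epoch_s,
    rest_epoch_s_range = rest_epoch_s_range,
    erd_band_hz = erd_band_hz,
    erd_depth = erd_depth,
    osc_amplitude = osc_amplitude,
    osc_burst_hz = osc_burst_hz,
    motor_channels = motor_channels,
    noise_sd = noise_sd,
    line_freq_hz = line_freq_hz,
    line_amplitude = line_amplitude,
    passband_hz = passband_hz,
    seed = as.integer(seed)
  ), class = "mi_synthetic_spec")
}

#' Default channel labels for a given montage size
#'
#' The first 22 labels cover the standard 10-20 positions plus the
#' fronto-central row (FC3/FCz/FC4) used over the hand motor area.
#'
#' @param n number of labels requested (max 24).
#' @return character vector of length `n`.
#' @export
default_channel_labels <- function(n) {
  vocab <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
             "FC3", "FCz", "FC4",
             "T3", "C3", "Cz", "C4", "T4",
             "T5", "P3", "Pz", "P4", "T6",
             "O1", "O2", "C5", "C6")
  if (n > length(vocab)) {
    stop("at most ", length(vocab), " default labels available; supply ",
         "`channel_labels` explicitly")
  }
  vocab[seq_len(n)]
}

#' Generate a labeled synthetic EEG recording
#'
#' Lays the events of all classes end-to-end in seeded random order, fills
#' every channel with band-limited Gaussian background noise, adds the
#' onset-locked narrow-band oscillation (attenuated by `erd_depth` during
#' movement-class epochs) on the motor channels, and optionally adds a mains
#' sinusoid to every channel.
#'
#' @param spec an [synthetic_spec()] object.
#' @return an `mi_recording`: list with `data` (channels x samples matrix),
#'   `sampling_rate_hz`, `channel_labels` and `events` (data.frame of 1-based
#'   `onset_sample`, `class_label`, `n_samples`).
#' @export
generate_recording <- function(spec) {
  if (!inherits(spec, "mi_synthetic_spec")) {
    stop("`spec` must be built with synthetic_spec()")
  }
  fs <- spec$sampling_rate_hz
  with_seed(spec$seed, {
    labels <- sample(rep(spec$classes, each = spec$trials_per_class))
    dur_s <- ifelse(labels == "rest",
                    runif(length(labels), spec$rest_epoch_s_range[1],
                          spec$rest_epoch_s_range[2]),
                    spec$movement_epoch_s)
    len <- as.integer(round(dur_s * fs))
    if (any(len < 2)) {
      stop("epoch lengths of ", min(len), " samples do not fit: increase the ",
           "epoch durations or the sampling rate")
    }
    onset <- as.integer(cumsum(c(1L, len))[seq_along(len)])
    n_total <- sum(len)

    data <- matrix(rnorm(spec$n_channels * n_total), nrow = spec$n_channels)
    data <- bandpass_rows(data, spec$passband_hz[1],
                          spec$passband_hz[2], fs)
    # the delivered (band-limited) background noise has sd = noise_sd
    data <- data * (spec$noise_sd / apply(data, 1L, sd))
    rownames(data) <- spec$channel_labels

    f0 <- mean(spec$erd_band_hz)
    osc <- numeric(n_total)
    for (i in seq_along(labels)) {
      amp <- spec$osc_amplitude *
        if (labels[i] == "rest") 1 else sqrt(1 - spec$erd_depth)
      idx <- onset[i]:(onset[i] + len[i] - 1L)
      tt <- (seq_len(len[i]) - 1L) / fs
      env <- if (spec$osc_burst_hz > 0) {
        # unit-RMS burst envelope: E[sin^12] = choose(12,6)/2^12 over a period,
        # so the oscillation's band power stays amp^2/2 regardless of bursting
        sin(pi * spec$osc_burst_hz * tt)^6 / sqrt(924 / 4096)
      } else 1
      osc[idx] <- amp * env * sin(2 * pi * f0 * tt)
    }
    for (ch in spec$motor_channels) {
      data[ch, ] <- data[ch, ] + osc
    }

    if (!is.null(spec$line_freq_hz) && spec$line_amplitude > 0) {
      mains <- spec$line_amplitude *
        sin(2 * pi * spec$line_freq_hz * (seq_len(n_total) - 1L) / fs)
      data <- sweep(data, 2L, mains, "+")
    }

    new_recording(data, fs, spec$channel_labels,
                  data.frame(onset_sample = onset, class_label = labels,
                             n_samples = len, stringsAsFactors = FALSE))
  })
}

# Internal constructor with invariant checks.
new_recording <- function(data, sampling_rate_hz, channel_labels, events) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_labels))
  if (anyDuplicated(channel_labels)) stop("duplicate channel labels rejected")
  if (nrow(events) > 0) {
    if (is.unsorted(events$onset_sample)) {
      events <- events[order(events$onset_sample), , drop = FALSE]
    }
    if (any(events$onset_sample + events$n_samples - 1L > ncol(data))) {
      stop("event extends beyond the end of the recording")
    }
  }
  structure(list(data = data,
                 sampling_rate_hz = sampling_rate_hz,
                 channel_labels = channel_labels,
                 events = events),
            class = "mi_recording")
}

#' @export
print.mi_recording <- function(x, ...) {
  cat(sprintf("<mi_recording> %d channels x %d samples @ %g Hz, %d events (%s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate_hz, nrow(x$events),
              paste(unique(x$events$class_label), collapse = ", ")))
  invisible(x)
}

#' @export
print.mi_synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("<mi_synthetic_spec> %d ch @ %g Hz, classes: %s, ",
                     "%d trials/class, ERD depth %.2f in %g-%g Hz on %s\n"),
              x$n_channels, x$sampling_rate_hz,
              paste(x$classes, collapse = ","), x$trials_per_class,
              x$erd_depth, x$erd_band_hz[1], x$erd_band_hz[2],
              paste(x$motor_channels, collapse = ",")))
  invisible(x)
}
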