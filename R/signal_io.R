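#' Write a recording or epoch set to the native on-disk format
#'
#' The native format is a directory holding one tab-delimited matrix per
#' record (channels as rows, full double precision) plus a `manifest.json`
#' describing the sampling rate, channel labels, class labels, event table
#' (for recordings) or epoch lengths (for epoch sets), file list and a free
#' provenance string. It is plain text, language-neutral and round-trip safe.
#'
#' @param x an `mi_recording` or an `mi_epochs` list (see [epoch_recording()]).
#' @param path directory to create (must not already contain a manifest).
#' @param provenance free-text provenance string stored in the manifest.
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(x, path, provenance = "mieeg") {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create dataset directory ", path)
  manifest_path <- file.path(path, "manifest.json")

  if (inherits(x, "mi_recording")) {
    file <- "signals.tsv"
    data.table::fwrite(as.data.frame(x$data), file.path(path, file),
                       sep = "\t", col.names = FALSE)
    manifest <- list(
      format = "mieeg-dataset/1",
      kind = "recording",
      sampling_rate_hz = x$sampling_rate_hz,
      channel_labels = x$channel_labels,
      class_labels = unique(x$events$class_label),
      files = file,
      events = x$events,
      provenance = provenance
    )
  } else if (inherits(x, "mi_epochs")) {
    if (length(x$epochs) == 0) stop("no epochs")
    files <- sprintf("epoch_%04d.tsv", seq_along(x$epochs))
    for (i in seq_along(x$epochs)) {
      data.table::fwrite(as.data.frame(x$epochs[[i]]$data),
                         file.path(path, files[i]),
                         sep = "\t", col.names = FALSE)
    }
    manifest <- list(
      format = "mieeg-dataset/1",
      kind = "epochs",
      sampling_rate_hz = x$sampling_rate_hz,
      channel_labels = x$channel_labels,
      class_labels = unique(vapply(x$epochs, `[[`, "", "class_label")),
      epoch_length_samples = x$epoch_length_samples,
      files = files,
      epoch_class = vapply(x$epochs, `[[`, "", "class_label"),
      epoch_onset = vapply(x$epochs, `[[`, 0L, "onset_sample"),
      provenance = provenance
    )
  } else {
    stop("`x` must be an mi_recording or mi_epochs object")
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(manifest_path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path dataset directory (or the manifest path itself).
#' @return an `mi_recording` or `mi_epochs` object, per the manifest `kind`.
#' @export
read_dataset <- function(path) {
  manifest_path <- if (dir.exists(path)) file.path(path, "manifest.json") else path
  if (!file.exists(manifest_path)) stop("no manifest found at ", path)
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  base <- dirname(manifest_path)
  missing <- m$files[!file.exists(file.path(base, m$files))]
  if (length(missing)) {
    stop("manifest references missing files: ", paste(missing, collapse = ", "))
  }
  read_mat <- function(f) {
    as.matrix(data.table::fread(file.path(base, f), sep = "\t", header = FALSE))
  }
  if (identical(m$kind, "recording")) {
    events <- as.data.frame(m$events)
    if (!all(events$class_label %in% m$class_labels)) {
      stop("event labels not covered by manifest class_labels")
    }
    data <- read_mat(m$files[1])
    dimnames(data) <- list(m$channel_labels, NULL)
    new_recording(data, m$sampling_rate_hz, m$channel_labels, events)
  } else if (identical(m$kind, "epochs")) {
    if (!all(m$epoch_class %in% m$class_labels)) {
      stop("epoch labels not covered by manifest class_labels")
    }
    epochs <- lapply(seq_along(m$files), function(i) {
      d <- read_mat(m$files[i])
      dimnames(d) <- list(m$channel_labels, NULL)
      list(data = d, class_label = m$epoch_class[i],
           onset_sample = m$epoch_onset[i])
    })
    structure(list(epochs = epochs,
                   sampling_rate_hz = m$sampling_rate_hz,
                   channel_labels = m$channel_labels,
                   epoch_length_samples = m$epoch_length_samples),
              class = "mi_epochs")
  } else {
    stop("unknown dataset kind: ", m$kind)
  }
}

#' Read an EDF (European Data Format) file as a recording
#'
#' Minimal read-only EDF adapter: parses the fixed-width ASCII header and the
#' 16-bit little-endian sample records, applies the per-signal physical
#' scaling, and returns the requested channels. Sample counts are preserved
#' exactly; annotations/events are not parsed.
#'
#' @param path EDF file path.
#' @param channel_subset channel labels to keep; `NULL` keeps all.
#' @return an `mi_recording` (with an empty event table).
#' @export
read_edf <- function(path, channel_subset = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd_num <- function(n) as.numeric(rd_str(n))
  rd_str(8)                       # version
  rd_str(80); rd_str(80)          # patient, recording id
  rd_str(8); rd_str(8)            # start date, time
  rd_num(8)                       # header bytes
  rd_str(44)                      # reserved
  n_records <- rd_num(8)
  record_dur <- rd_num(8)
  ns <- as.integer(rd_num(4))
  fld <- function(width, numeric = FALSE) {
    vapply(seq_len(ns), function(i) rd_str(width), "")
  }
  labels <- fld(16)
  fld(80)                          # transducer
  fld(8)                           # physical dimension
  phys_min <- as.numeric(fld(8))
  phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8))
  dig_max <- as.numeric(fld(8))
  fld(80)                          # prefiltering
  spr <- as.integer(fld(8))        # samples per record
  fld(32)                          # reserved

  keep <- if (is.null(channel_subset)) labels else channel_subset
  missing <- setdiff(keep, labels)
  if (length(missing)) {
    stop("channel(s) ", paste(missing, collapse = ", "),
         " not in EDF file; available: ", paste(labels, collapse = ", "))
  }
  total <- spr * n_records
  data <- matrix(0, nrow = length(keep), ncol = max(total[labels %in% keep]))
  rownames(data) <- keep
  offsets <- c(0L, cumsum(spr))
  for (r in seq_len(n_records)) {
    rec <- readBin(con, "integer", n = sum(spr), size = 2L,
                   signed = TRUE, endian = "little")
    for (j in seq_along(keep)) {
      k <- match(keep[j], labels)
      dig <- rec[(offsets[k] + 1L):offsets[k + 1L]]
      scale <- (phys_max[k] - phys_min[k]) / (dig_max[k] - dig_min[k])
      data[j, ((r - 1L) * spr[k] + 1L):(r * spr[k])] <-
        phys_min[k] + (dig - dig_min[k]) * scale
    }
  }
  fs <- spr[match(keep[1], labels)] / record_dur
  new_recording(data, fs, keep,
                data.frame(onset_sample = integer(), class_label = character(),
                           n_samples = integer(), stringsAsFactors = FALSE))
}

#' Write a recording as a minimal EDF file
#'
#' Companion writer to [read_edf()], mainly for building test fixtures and
#' exchanging recordings with EDF-based tools. Samples are quantized to the
#' EDF 16-bit integer range over each channel's observed amplitude span; any
#' trailing partial data record is dropped.
#'
#' @param recording an `mi_recording`.
#' @param path output file path.
#' @param record_duration_s data-record length in seconds;
#'   `sampling_rate_hz * record_duration_s` must be a whole number.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, record_duration_s = 1) {
  x <- recording
  spr <- x$sampling_rate_hz * record_duration_s
  if (abs(spr - round(spr)) > 1e-9) {
    stop("sampling_rate_hz * record_duration_s must be an integer")
  }
  spr <- as.integer(round(spr))
  ns <- nrow(x$data)
  n_records <- ncol(x$data) %/% spr
  if (n_records < 1) stop("recording shorter than one data record")

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) {
    s <- substr(sprintf("%-*s", width, s), 1L, width)
    writeChar(s, con, nchars = width, eos = NULL)
  }
  header_bytes <- 256L + 256L * ns
  wr("0", 8)
  wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.01", 8); wr("00.00.00", 8)
  wr(format(header_bytes), 8)
  wr("", 44)
  wr(format(n_records), 8)
  wr(format(record_duration_s), 8)
  wr(format(ns), 4)

  phys_max <- apply(abs(x$data), 1L, max)
  phys_max[phys_max == 0] <- 1
  for (l in x$channel_labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", -phys_max[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", phys_max[i]), 8)
  for (i in seq_len(ns)) wr("-32767", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(format(spr), 8)
  for (i in seq_len(ns)) wr("", 32)

  for (r in seq_len(n_records)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(ns)) {
      dig <- as.integer(round(x$data[i, idx] / phys_max[i] * 32767))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
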