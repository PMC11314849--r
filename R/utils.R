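#' @importFrom stats rnorm runif var sd cor pt predict
#' @importFrom utils head tail
NULL

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the session RNG, evaluates `expr`, and restores whatever RNG state
#' existed before the call, so seeded package internals never perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a vector of sub-seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Zero-phase Butterworth bandpass
#'
#' Fourth-order Butterworth bandpass (order-2 analog prototype, 4 poles)
#' applied forward-backward, so the passband stays flat, edges fall at the
#' corner frequencies, and no phase delay is introduced. Degenerates to a
#' high- or low-pass when one edge is absent (`lo = 0` or `hi >= fs/2`).
#'
#' @param x numeric vector (one channel).
#' @param lo,hi band edges in Hz.
#' @param fs sampling rate in Hz.
#' @return filtered vector, same length as `x`.
#' @keywords internal
bandpass_zero_phase <- function(x, lo, hi, fs) {
  nyq <- fs / 2
  if (hi <= lo) stop("bandpass: `hi` must exceed `lo`")
  y <- as.numeric(x)
  filt <- if (lo > 0 && hi < nyq) {
    signal::butter(2, c(lo, hi) / nyq, type = "pass")
  } else if (lo > 0) {
    signal::butter(2, lo / nyq, type = "high")
  } else if (hi < nyq) {
    signal::butter(2, hi / nyq, type = "low")
  } else {
    return(y)
  }
  signal::filtfilt(filt, y)
}

# Apply bandpass_zero_phase to every row of a channels x samples matrix.
bandpass_rows <- function(mat, lo, hi, fs) {
  out <- t(apply(mat, 1L, bandpass_zero_phase, lo = lo, hi = hi, fs = fs))
  dimnames(out) <- dimnames(mat)
  out
}

# Tiny FNV-1a hash of a character scalar, for config fingerprints in tables.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = " "))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Shared montage vocabulary (10-20 labels used throughout the experiments).
montage_vocabulary <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC3", "FCz", "FC4",
    "T3", "C5", "C3", "Cz", "C4", "C6", "T4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "O2")
}

# Left/right hemisphere tag for a 10-20 label: odd digit = left, even = right,
# z = midline.
hemisphere <- function(labels) {
  suffix <- sub("^[A-Za-z]+", "", labels)
  ifelse(suffix == "z" | suffix == "",
         "midline",
         ifelse(as.integer(suffix) %% 2L == 1L, "left", "right"))
}
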