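#' Build the fixed filter-bank plan
#'
#' The known bands are fixed: delta 0.5-4, theta 4-8, alpha 8-12 Hz; five
#' 4-Hz sub-beta bands 12-16, 16-20, 20-24, 24-28, 28-32; four 4-Hz sub-gamma
#' bands 30-34, 34-38, 38-42, 42-46 (the 28-32/30-34 overlap is part of the
#' plan and kept as printed). Unknown bands then tile
#' `[unknown_start_hz, frequency_limit_hz]` in 5-Hz steps, the final tile
#' truncated at the limit.
#'
#' @param frequency_limit_hz upper frequency limit of the data (bandwidth).
#' @param unknown_start_hz 55 or 65, chosen by the provenance of the data
#'   (55 with 50-Hz mains, 65 with 60-Hz mains).
#' @param strict if `TRUE`, a limit below 46 Hz (which truncates the known
#'   plan) is an error instead of a warning.
#' @return an `mi_filter_bank`: data.frame with `name`, `lo_hz`, `hi_hz`, plus
#'   attributes `frequency_limit_hz` and `unknown_start_hz`.
#' @export
build_filter_bank <- function(frequency_limit_hz, unknown_start_hz = 55,
                              strict = FALSE) {
  if (!unknown_start_hz %in% c(55, 65)) {
    stop("`unknown_start_hz` must be 55 or 65")
  }
  known <- data.frame(
    name = c("delta", "theta", "alpha",
             paste0("sub-beta-", 1:5), paste0("sub-gamma-", 1:4)),
    lo_hz = c(0.5, 4, 8, 12, 16, 20, 24, 28, 30, 34, 38, 42),
    hi_hz = c(4, 8, 12, 16, 20, 24, 28, 32, 34, 38, 42, 46),
    stringsAsFactors = FALSE
  )
  if (frequency_limit_hz < 46) {
    msg <- paste0("frequency limit ", frequency_limit_hz,
                  " Hz truncates the known band plan (needs >= 46 Hz)")
    if (strict) stop(msg)
    warning(msg)
    known <- known[known$hi_hz <= frequency_limit_hz, , drop = FALSE]
  }
  bands <- known
  if (frequency_limit_hz > unknown_start_hz) {
    lo <- seq(unknown_start_hz, frequency_limit_hz - 1e-9, by = 5)
    hi <- pmin(lo + 5, frequency_limit_hz)
    bands <- rbind(bands, data.frame(
      name = paste0("unknown-", seq_along(lo)),
      lo_hz = lo, hi_hz = hi, stringsAsFactors = FALSE))
  }
  rownames(bands) <- NULL
  structure(bands,
            frequency_limit_hz = frequency_limit_hz,
            unknown_start_hz = unknown_start_hz,
            class = c("mi_filter_bank", "data.frame"))
}

#' Decompose one signal through the filter bank
#'
#' Row k of the output is the zero-phase bandpass of the input at band k, in
#' the bank's band order. Bands whose upper edge reaches Nyquist are dropped
#' with a warning (or an error under `strict`).
#'
#' @param x numeric vector, one signal.
#' @param fb an `mi_filter_bank`.
#' @param fs sampling rate in Hz.
#' @param strict error instead of dropping super-Nyquist bands.
#' @return n_bands x samples matrix with band names as row names.
#' @export
apply_filter_bank <- function(x, fb, fs, strict = FALSE) {
  stopifnot(inherits(fb, "mi_filter_bank"))
  ok <- fb$hi_hz < fs / 2
  if (any(!ok)) {
    msg <- paste0(sum(!ok), " band(s) at or above Nyquist (", fs / 2,
                  " Hz) for fs = ", fs)
    if (strict) stop(msg)
    warning(msg)
  }
  bands <- fb[ok, , drop = FALSE]
  out <- t(vapply(seq_len(nrow(bands)), function(k) {
    bandpass_zero_phase(x, bands$lo_hz[k], bands$hi_hz[k], fs)
  }, numeric(length(x))))
  rownames(out) <- bands$name
  out
}

# Trace-normalized covariance of a bands x samples matrix.
normalized_covariance <- function(M) {
  C <- tcrossprod(M - rowMeans(M)) / (ncol(M) - 1)
  C / sum(diag(C))
}

#' Fit the two-class common-spatial-pattern comparator
#'
#' Computes trace-normalized covariances `C_A`, `C_B` of the two band-stacked
#' signals and simultaneously diagonalizes `(C_A, C_A + C_B)`: whiten the
#' composite, eigendecompose the whitened `C_A`, and keep the `m` spatial
#' filters with the largest eigenvalues plus the `m` with the smallest (the
#' directions maximizing `var_A / (var_A + var_B)` and its inverse).
#' Eigenvalues lie in `[0, 1]` and are returned in descending order.
#'
#' @param A,B n_bands x samples matrices (same band count; sample counts at
#'   least the band count).
#' @param m reduced-dimension parameter, `1 <= m <= floor(n_bands/2)`.
#' @param ridge relative ridge added to the composite covariance when it is
#'   numerically singular (fraction of its trace).
#' @return an `mi_cssp_model`: `projection` (2m x n_bands spatial filters,
#'   top-m rows first), `m`, `eigenvalues` (all n_bands, descending),
#'   `band_order`.
#' @export
cssp_fit <- function(A, B, m, ridge = 1e-9) {
  if (nrow(A) != nrow(B)) stop("`A` and `B` must have the same band count")
  n_bands <- nrow(A)
  if (ncol(A) < n_bands || ncol(B) < n_bands) {
    stop("sample counts must be at least the band count")
  }
  if (m < 1 || m > floor(n_bands / 2)) {
    stop("`m` must be between 1 and floor(n_bands/2) = ", floor(n_bands / 2))
  }
  Ca <- normalized_covariance(A)
  Cb <- normalized_covariance(B)
  R <- Ca + Cb
  er <- eigen(R, symmetric = TRUE)
  if (min(er$values) <= max(er$values) * 1e-12) {
    R <- R + ridge * sum(diag(R)) * diag(n_bands)
    er <- eigen(R, symmetric = TRUE)
    if (min(er$values) <= max(er$values) * 1e-12) {
      stop("singular composite covariance even after ridge regularization; ",
           "increase `ridge` or check for constant bands")
    }
  }
  P <- diag(1 / sqrt(er$values), n_bands) %*% t(er$vectors)
  S <- P %*% Ca %*% t(P)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  filters <- es$vectors                     # columns, eigenvalues descending
  W <- t(filters) %*% P                     # rows = spatial filters
  sel <- c(seq_len(m), n_bands - seq_len(m) + 1L)
  structure(list(projection = W[sel, , drop = FALSE],
                 m = as.integer(m),
                 eigenvalues = pmin(pmax(es$values, 0), 1),
                 band_order = rownames(A)),
            class = "mi_cssp_model")
}

# Per-band log-variance profile of X under a fitted model: each band's
# variance weighted by the squared projection coefficients of the 2m filters.
cssp_band_profile <- function(model, X) {
  v <- apply(X, 1L, var)
  w2 <- colSums(model$projection^2)
  log(w2 * v + .Machine$double.xmin)
}

#' Paired comparative feature vectors f_a and f_b
#'
#' `f_a` is the per-band log-variance profile of `A` under the model fitted
#' with `(A, B)`; `f_b` is the profile of `B` under the model fitted with the
#' roles inverted. Both have one entry per band (the number of filters in the
#' bank).
#'
#' @param model an `mi_cssp_model` fitted with `cssp_fit(A, B, m)`.
#' @param A,B the two band-stacked signals.
#' @return an `mi_cssp_features`: list with `f_a`, `f_b` (length n_bands) and
#'   `class_pair`.
#' @export
cssp_features <- function(model, A, B) {
  stopifnot(inherits(model, "mi_cssp_model"))
  if (nrow(A) != length(model$band_order) && nrow(A) != ncol(model$projection)) {
    stop("band count of `A` does not match the model")
  }
  model_ba <- cssp_fit(B, A, model$m)
  structure(list(f_a = cssp_band_profile(model, A),
                 f_b = cssp_band_profile(model_ba, B),
                 class_pair = attr(model, "class_pair")),
            class = "mi_cssp_features")
}

#' Fold-aware FB-CSSP feature dataset for one class pair
#'
#' Exactly two classes can be compared at once. Each selected trial is
#' decomposed through the filter bank per electrode (rows stacked
#' electrode-major: electrode 1's bands, then electrode 2's, ...). Trials are
#' assigned to stratified folds; within each fold the comparator is fitted on
#' the training trials only (their band stacks concatenated per class) and the
#' per-band log-variance feature vector of every trial is computed under that
#' fold's projection - so no test-trial information leaks into the model.
#'
#' @param epochs an `mi_epochs` object.
#' @param electrode_labels electrodes to stack.
#' @param class_pair exactly two class labels.
#' @param fb an `mi_filter_bank`; the default tiles up to the data's useful
#'   bandwidth - 100 Hz (the passband of the kHz-rate recordings emulated
#'   here) or just below Nyquist for lower sampling rates, whichever is
#'   smaller.
#' @param m reduced-dimension parameter (default 1).
#' @param n_trials trials per class.
#' @param k_folds number of folds.
#' @param seed seed for trial subsampling and fold assignment.
#' @return data.frame with one row per (fold, trial): `fold`, `role`
#'   (`"train"`/`"test"`), `trial_id`, `class_label`, and one feature column
#'   per band row (`f_<band>`), plus a `config` attribute.
#' @export
build_cssp_feature_dataset <- function(epochs, electrode_labels, class_pair,
                                       fb = build_filter_bank(
                                         min(100, epochs$sampling_rate_hz / 2 - 1)),
                                       m = 1, n_trials = 20, k_folds = 10,
                                       seed = 1L) {
  stopifnot(inherits(epochs, "mi_epochs"))
  if (length(class_pair) != 2) {
    stop("the comparator takes exactly two classes at once; got ",
         length(class_pair))
  }
  fs <- epochs$sampling_rate_hz
  by_class <- split(epochs$epochs,
                    vapply(epochs$epochs, `[[`, "", "class_label"))
  seeds <- derive_seeds(seed, 3L)
  trials <- list()
  labels <- character()
  for (ci in 1:2) {
    cl <- class_pair[ci]
    pool <- by_class[[cl]]
    if (length(pool) < n_trials) {
      stop(n_trials, " trials requested for class '", cl, "' but only ",
           length(pool), " available")
    }
    pick <- with_seed(seeds[ci], sample(seq_along(pool), n_trials))
    for (e in pool[pick]) {
      stack <- do.call(rbind, lapply(electrode_labels, function(el) {
        bs <- suppressWarnings(apply_filter_bank(e$data[el, ], fb, fs))
        rownames(bs) <- paste0(el, ".", rownames(bs))
        bs
      }))
      trials[[length(trials) + 1L]] <- stack
      labels <- c(labels, cl)
    }
  }
  folds <- stratified_folds(labels, k_folds, seeds[3L])
  band_names <- rownames(trials[[1]])

  rows <- list()
  for (f in seq_len(k_folds)) {
    train <- which(folds != f)
    A <- do.call(cbind, trials[train[labels[train] == class_pair[1]]])
    B <- do.call(cbind, trials[train[labels[train] == class_pair[2]]])
    model <- cssp_fit(A, B, m)
    feats <- t(vapply(trials, function(tr) cssp_band_profile(model, tr),
                      numeric(length(band_names))))
    colnames(feats) <- paste0("f_", band_names)
    rows[[f]] <- data.frame(fold = f,
                            role = ifelse(folds == f, "test", "train"),
                            trial_id = seq_along(trials),
                            class_label = labels,
                            feats, stringsAsFactors = FALSE,
                            check.names = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "config") <- config_hash(list(electrode_labels, class_pair, m,
                                          n_trials, k_folds, seed,
                                          attr(fb, "frequency_limit_hz")))
  res
}

#' Cross-validated evaluation of a fold-aware CSSP feature table
#'
#' Trains the classifier per fold on the `train`-role rows and scores the
#' `test`-role rows, honoring the leakage-free features of
#' [build_cssp_feature_dataset()].
#'
#' @param features output of [build_cssp_feature_dataset()].
#' @param classifier_id classifier passed to [fit_classifier()]; the default
#'   Gaussian naive-Bayes discriminant is the standard choice for
#'   spatial-pattern log-variance features, whose training sets are small
#'   relative to the band count.
#' @param seed seed forwarded to the classifier.
#' @param ... classifier hyperparameters.
#' @return an `mi_classification_result` (see [crossval_evaluate()]).
#' @export
crossval_evaluate_cssp <- function(features, classifier_id = "nb", seed = 1L,
                                   ...) {
  feat_cols <- grep("^f_", names(features), value = TRUE)
  k_folds <- max(features$fold)
  classes <- sort(unique(features$class_label))
  truth <- character()
  pred <- character()
  fold_of <- integer()
  for (f in seq_len(k_folds)) {
    blk <- features[features$fold == f, , drop = FALSE]
    tr <- blk[blk$role == "train", , drop = FALSE]
    te <- blk[blk$role == "test", , drop = FALSE]
    if (nrow(te) == 0) next
    clf <- fit_classifier(as.matrix(tr[, feat_cols]), tr$class_label,
                          classifier_id = classifier_id, seed = seed, ...)
    ph <- predict_classifier(clf, as.matrix(te[, feat_cols]))
    truth <- c(truth, te$class_label)
    pred <- c(pred, ph)
    fold_of <- c(fold_of, rep(f, nrow(te)))
  }
  summarize_cv(truth, pred, fold_of, classes, classifier_id, k_folds, seed)
}
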