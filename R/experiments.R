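#' Configuration for a comparison-regime experiment sweep
#'
#' Describes one sweep: a comparison regime, a detector, the electrode sets,
#' trial counts and detector parameters to cross, the classes involved, and
#' the dataset source. Electrode labels are validated against the 10-20
#' montage vocabulary used throughout (C3, C4, Cz, P3, P4, Pz, F3, Fz, F4,
#' F7, F8, T5, T6, ...).
#'
#' @param regime `"general_vs_rest"` (all movement classes pooled against
#'   rest), `"specific_vs_rest"` (each movement class against rest), or
#'   `"specific_vs_specific"` (all pairwise class comparisons plus one
#'   multi-class confusion matrix; needs at least 3 classes).
#' @param detector `"fasticacorr"` or `"fbcssp"`.
#' @param electrode_sets list of electrode-label vectors, e.g.
#'   `list("C3", c("C3","C4"), c("C3","C4","P3"))`.
#' @param trial_counts trial counts to sweep (typically from 20, 50, 100, 150).
#' @param component_counts FastICACorr component counts (typically 10, 20).
#' @param m_values FB-CSSP reduced-dimension values (typically 1, 2, 5).
#' @param classes class labels present in the data.
#' @param dataset an [synthetic_spec()] (generated on demand) or a path to a
#'   dataset manifest written by [write_dataset()].
#' @param window_s epoch window in seconds.
#' @param n_components_repetitions extractions per class for the FastICACorr
#'   feature dataset.
#' @param feature_unit observation unit for FastICACorr features
#'   (`"run"` or `"pair"`; see [build_fastica_feature_dataset()]).
#' @param feature_template correlation template mode for FastICACorr
#'   (`"per_trial"` or `"mean"`; see [corr_features()]).
#' @param classifier_args classifier settings for every sweep cell (passed to
#'   [fit_classifier()] via the evaluators), e.g.
#'   `list(classifier_id = "svm", kernel = "linear")`. `NULL` uses the
#'   detector-specific defaults: a linear-kernel SVM for FastICACorr
#'   correlation profiles and the Gaussian naive-Bayes discriminant for
#'   FB-CSSP log-variance features.
#' @param k_folds cross-validation folds.
#' @param seed master seed; the whole report is reproducible from
#'   (config, seed).
#' @return an `mi_experiment_config`.
#' @export
experiment_config <- function(regime = c("general_vs_rest", "specific_vs_rest",
                                         "specific_vs_specific"),
                              detector = c("fasticacorr", "fbcssp"),
                              electrode_sets,
                              trial_counts = 20,
                              component_counts = 20,
                              m_values = 1,
                              classes = c("thumb", "index", "middle", "ring",
                                          "pinkie", "rest"),
                              dataset = synthetic_spec(),
                              window_s = 1,
                              n_components_repetitions = 20,
                              feature_unit = "run",
                              feature_template = "per_trial",
                              classifier_args = NULL,
                              k_folds = 10,
                              seed = 1L) {
  regime <- match.arg(regime)
  detector <- match.arg(detector)
  if (length(electrode_sets) == 0) stop("`electrode_sets` must be nonempty")
  if (!is.list(electrode_sets)) electrode_sets <- list(electrode_sets)
  vocab <- montage_vocabulary()
  bad <- setdiff(unlist(electrode_sets), vocab)
  if (length(bad)) {
    stop("electrode label(s) outside the montage vocabulary: ",
         paste(bad, collapse = ", "))
  }
  if (regime == "specific_vs_specific" && length(classes) < 3) {
    stop("specific_vs_specific needs at least 3 classes")
  }
  structure(list(regime = regime, detector = detector,
                 electrode_sets = electrode_sets,
                 trial_counts = trial_counts,
                 component_counts = component_counts,
                 m_values = m_values,
                 classes = classes,
                 dataset = dataset,
                 window_s = window_s,
                 n_components_repetitions = n_components_repetitions,
                 feature_unit = feature_unit,
                 feature_template = feature_template,
                 classifier_args = classifier_args,
                 k_folds = k_folds,
                 seed = as.integer(seed)),
            class = "mi_experiment_config")
}

# Load or generate the configured dataset and epoch it.
experiment_epochs <- function(cfg) {
  rec <- if (inherits(cfg$dataset, "mi_synthetic_spec")) {
    generate_recording(cfg$dataset)
  } else {
    read_dataset(cfg$dataset)
  }
  if (inherits(rec, "mi_epochs")) rec else epoch_recording(rec, cfg$window_s)
}

# The class comparisons a regime implies.
regime_comparisons <- function(regime, classes) {
  movement <- setdiff(classes, "rest")
  switch(regime,
    general_vs_rest = list(c("movement", "rest")),
    specific_vs_rest = lapply(movement, function(cl) c(cl, "rest")),
    specific_vs_specific = {
      combn(classes, 2, simplify = FALSE)
    })
}

#' Run an experiment sweep
#'
#' Executes the full Cartesian sweep of electrode sets x trial counts x
#' detector parameter (component counts for FastICACorr, m values for
#' FB-CSSP) x class comparisons of the regime, evaluating each cell with
#' stratified k-fold cross-validation. For `specific_vs_specific` with the
#' FastICACorr detector a multi-class confusion matrix over all classes is
#' additionally produced. Failed cells are recorded and the sweep continues.
#'
#' @param cfg an [experiment_config()].
#' @return an `mi_experiment_report`: `cells` (data.frame with one row per
#'   sweep cell: electrode set, trials, parameter, comparison, success rate,
#'   per-fold rates), `confusions` (named list of confusion matrices),
#'   `failures` (data.frame of failed cells and messages), and `config`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "mi_experiment_config"))
  epochs <- experiment_epochs(cfg)
  if (cfg$regime == "general_vs_rest") {
    epochs <- pool_movement_classes(epochs)
  }
  comparisons <- regime_comparisons(cfg$regime, cfg$classes)
  clf_args <- cfg$classifier_args
  if (is.null(clf_args)) {
    clf_args <- if (cfg$detector == "fasticacorr") {
      list(classifier_id = "svm", kernel = "linear")
    } else {
      list(classifier_id = "nb")
    }
  }
  params <- if (cfg$detector == "fasticacorr") cfg$component_counts else cfg$m_values
  param_name <- if (cfg$detector == "fasticacorr") "n_components" else "m"

  grid <- expand.grid(set = seq_along(cfg$electrode_sets),
                      trials = cfg$trial_counts,
                      param = params,
                      cmp = seq_along(comparisons))
  cell_seeds <- derive_seeds(cfg$seed, nrow(grid) + 1L)

  cells <- list()
  failures <- list()
  confusions <- list()
  for (g in seq_len(nrow(grid))) {
    set_labels <- cfg$electrode_sets[[grid$set[g]]]
    cmp <- comparisons[[grid$cmp[g]]]
    cell_id <- sprintf("%s|%d trials|%s=%g|%s",
                       paste(set_labels, collapse = "+"), grid$trials[g],
                       param_name, grid$param[g], paste(cmp, collapse = " vs "))
    res <- tryCatch({
      if (cfg$detector == "fasticacorr") {
        feats <- build_fastica_feature_dataset(
          epochs, set_labels, cmp,
          n_components = grid$param[g], n_trials = grid$trials[g],
          repetitions = cfg$n_components_repetitions,
          unit = cfg$feature_unit, template = cfg$feature_template,
          seed = cell_seeds[g])
        cols <- setdiff(names(feats),
                        c("class_label", "repetition", "config",
                          "component_index"))
        do.call(crossval_evaluate,
                c(list(feats[, cols, drop = FALSE], feats$class_label,
                       k_folds = cfg$k_folds, seed = cell_seeds[g]),
                  clf_args))
      } else {
        feats <- build_cssp_feature_dataset(
          epochs, set_labels, cmp, m = grid$param[g],
          n_trials = grid$trials[g], k_folds = cfg$k_folds,
          seed = cell_seeds[g])
        do.call(crossval_evaluate_cssp,
                c(list(feats, seed = cell_seeds[g]), clf_args))
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        cell = cell_id, message = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      cells[[length(cells) + 1L]] <- data.frame(
        electrode_set = paste(set_labels, collapse = "+"),
        n_trials = grid$trials[g],
        parameter = param_name,
        parameter_value = grid$param[g],
        comparison = paste(cmp, collapse = " vs "),
        success_rate = res$success_rate,
        min_fold_rate = min(res$per_fold_rates),
        max_fold_rate = max(res$per_fold_rates),
        stringsAsFactors = FALSE)
    }
  }

  if (cfg$regime == "specific_vs_specific" && cfg$detector == "fasticacorr") {
    for (si in seq_along(cfg$electrode_sets)) {
      set_labels <- cfg$electrode_sets[[si]]
      res <- tryCatch({
        feats <- build_fastica_feature_dataset(
          epochs, set_labels, cfg$classes,
          n_components = max(cfg$component_counts),
          n_trials = min(cfg$trial_counts),
          repetitions = cfg$n_components_repetitions,
          unit = cfg$feature_unit, template = cfg$feature_template,
          seed = cell_seeds[nrow(grid) + 1L])
        cols <- setdiff(names(feats),
                        c("class_label", "repetition", "config",
                          "component_index"))
        do.call(crossval_evaluate,
                c(list(feats[, cols, drop = FALSE], feats$class_label,
                       k_folds = cfg$k_folds,
                       seed = cell_seeds[nrow(grid) + 1L]),
                  clf_args))
      }, error = function(e) e)
      key <- paste(set_labels, collapse = "+")
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <- data.frame(
          cell = paste0("confusion|", key), message = conditionMessage(res),
          stringsAsFactors = FALSE)
      } else {
        confusions[[key]] <- res$confusion
      }
    }
  }

  structure(list(
    cells = if (length(cells)) do.call(rbind, cells) else
      data.frame(electrode_set = character()),
    confusions = confusions,
    failures = if (length(failures)) do.call(rbind, failures) else
      data.frame(cell = character(), message = character()),
    config = cfg),
    class = "mi_experiment_report")
}

#' @export
print.mi_experiment_report <- function(x, ...) {
  cat(sprintf("<mi_experiment_report> %s / %s: %d cells, %d confusion matrices, %d failures\n",
              x$config$regime, x$config$detector, nrow(x$cells),
              length(x$confusions), nrow(x$failures)))
  if (nrow(x$cells)) print(utils::head(x$cells, 10))
  invisible(x)
}

#' Per-component extraction timing
#'
#' Runs the FastICACorr extraction and reports the wall-clock time each
#' component took, per repetition. Timing is hardware-dependent and is
#' reported only, never asserted.
#'
#' @param epochs an `mi_epochs` object.
#' @param electrode_labels electrodes to stack.
#' @param class_label class whose trials are extracted.
#' @param n_components components per extraction.
#' @param n_trials trials per extraction.
#' @param repetitions number of repeated extractions.
#' @param seed master seed.
#' @return data.frame with `repetition`, `component`, `seconds`, `converged`.
#' @export
time_components <- function(epochs, electrode_labels, class_label,
                            n_components = 20, n_trials = 20,
                            repetitions = 1, seed = 1L) {
  seeds <- derive_seeds(seed, repetitions)
  out <- lapply(seq_len(repetitions), function(rp) {
    tm <- assemble_trial_matrix(epochs, electrode_labels, class_label,
                                n_trials = n_trials)
    ref <- make_reference_row(ncol(tm$rows), seeds[rp])
    obs <- build_observation_matrix(tm, ref)
    comps <- fastica_extract(obs, n_components, seed = seeds[rp])
    data.frame(repetition = rp, component = seq_len(n_components),
               seconds = comps$component_seconds,
               converged = comps$converged)
  })
  do.call(rbind, out)
}
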