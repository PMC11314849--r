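# Stratified fold assignment: every class's observations are spread across
# folds as evenly as possible; seeded and deterministic.
stratified_folds <- function(labels, k_folds, seed) {
  labels <- as.character(labels)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k_folds) {
        stop("class '", cl, "' has only ", length(idx),
             " observation(s) for ", k_folds, "-fold cross-validation")
      }
      folds[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
    }
  })
  folds
}

#' Train a classifier
#'
#' `classifier_id = "svm"` fits a support-vector machine (via libsvm; RBF
#' kernel by default, one-vs-one voting for more than two classes).
#' `classifier_id = "nb"` fits a Gaussian naive-Bayes model (diagonal
#' class-conditional covariances) - the shrinkage-free analogue of the
#' diagonal linear discriminant that is standard for spatial-pattern
#' log-variance features, where training sets are small relative to the
#' feature count. Alternatively, any model can plug in by passing a list
#' `list(train = function(x, y, seed) model, predict = function(model, x)
#' labels)` as `classifier_id`.
#'
#' @param features numeric matrix/data.frame of observations x features.
#' @param labels class labels (one per observation, at least two classes).
#' @param classifier_id `"svm"`, `"nb"`, or a train/predict list (see
#'   Details).
#' @param seed seed (forwarded to custom classifiers; the SVM fit itself is
#'   deterministic given the data).
#' @param kernel,cost,gamma SVM hyperparameters (`gamma = NULL` uses the
#'   libsvm default 1/n_features).
#' @return an `mi_classifier`.
#' @export
fit_classifier <- function(features, labels, classifier_id = "svm", seed = 1L,
                           kernel = "radial", cost = 1, gamma = NULL) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2) {
    stop("training data contains a single class ('", levels(labels), "')")
  }
  if (is.list(classifier_id)) {
    model <- classifier_id$train(features, labels, seed)
    structure(list(kind = "custom", model = model,
                   predict_fun = classifier_id$predict,
                   levels = levels(labels)),
              class = "mi_classifier")
  } else if (identical(classifier_id, "svm")) {
    args <- list(x = features, y = labels, kernel = kernel, cost = cost,
                 scale = apply(features, 2, function(col) var(col) > 0))
    if (!is.null(gamma)) args$gamma <- gamma
    model <- do.call(e1071::svm, args)
    structure(list(kind = "svm", model = model, levels = levels(labels)),
              class = "mi_classifier")
  } else if (identical(classifier_id, "nb")) {
    model <- e1071::naiveBayes(features, labels)
    structure(list(kind = "nb", model = model, levels = levels(labels)),
              class = "mi_classifier")
  } else {
    stop("unknown classifier_id")
  }
}

#' Predict with a fitted classifier
#'
#' @param classifier an `mi_classifier` from [fit_classifier()].
#' @param features observations x features matrix.
#' @return character vector of predicted labels.
#' @export
predict_classifier <- function(classifier, features) {
  if (!inherits(classifier, "mi_classifier")) {
    stop("predict before train: fit a classifier with fit_classifier() first")
  }
  features <- as.matrix(features)
  if (classifier$kind == "custom") {
    as.character(classifier$predict_fun(classifier$model, features))
  } else {
    as.character(predict(classifier$model, features))
  }
}

#' Train an SVM (convenience wrapper)
#'
#' @inheritParams fit_classifier
#' @param hyperparams named list of SVM hyperparameters
#'   (`kernel`, `cost`, `gamma`).
#' @return an `mi_classifier`.
#' @export
svm_train <- function(features, labels, hyperparams = list(), seed = 1L) {
  do.call(fit_classifier,
          c(list(features = features, labels = labels,
                 classifier_id = "svm", seed = seed), hyperparams))
}

#' @rdname svm_train
#' @param classifier fitted `mi_classifier`.
#' @export
svm_predict <- function(classifier, features) {
  predict_classifier(classifier, features)
}

# Assemble a classification result from pooled predictions.
summarize_cv <- function(truth, pred, fold_of, classes, classifier_id,
                         k_folds, seed) {
  pred <- factor(pred, levels = classes)
  truth <- factor(truth, levels = classes)
  success_rate <- 100 * mean(pred == truth)
  per_fold <- vapply(sort(unique(fold_of)), function(f) {
    100 * mean((pred == truth)[fold_of == f])
  }, 0)
  counts <- table(truth, pred)
  confusion <- 100 * sweep(unclass(counts), 1L, pmax(rowSums(counts), 1L), "/")
  structure(list(success_rate = success_rate,
                 confusion = confusion,
                 per_fold_rates = per_fold,
                 class_counts = as.integer(table(truth)),
                 classes = classes,
                 classifier_id = if (is.list(classifier_id)) "custom" else classifier_id,
                 k_folds = k_folds,
                 seed = seed),
            class = "mi_classification_result")
}

#' Stratified k-fold cross-validated classification
#'
#' Assigns observations to stratified folds, trains the classifier on each
#' fold's training split only, scores the held-out split, and pools the
#' predictions into a success rate (percent correct) and a row-normalized
#' confusion matrix (percent). Deterministic given `seed`.
#'
#' @param features observations x features matrix/data.frame.
#' @param labels class labels, at least two classes, each with at least
#'   `k_folds` observations.
#' @param k_folds number of folds (default 10).
#' @param classifier_id passed to [fit_classifier()].
#' @param seed seed controlling fold assembly.
#' @param ... classifier hyperparameters.
#' @return an `mi_classification_result`: `success_rate` (percent),
#'   `confusion` (k x k, rows sum to 100), `per_fold_rates`, `classifier_id`,
#'   `k_folds`, `seed`.
#' @export
crossval_evaluate <- function(features, labels, k_folds = 10,
                              classifier_id = "svm", seed = 1L, ...) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least two classes")
  folds <- stratified_folds(labels, k_folds, seed)
  truth <- character()
  pred <- character()
  fold_of <- integer()
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    clf <- fit_classifier(features[tr, , drop = FALSE], labels[tr],
                          classifier_id = classifier_id, seed = seed, ...)
    ph <- predict_classifier(clf, features[!tr, , drop = FALSE])
    truth <- c(truth, labels[!tr])
    pred <- c(pred, ph)
    fold_of <- c(fold_of, rep(f, sum(!tr)))
  }
  summarize_cv(truth, pred, fold_of, sort(unique(labels)), classifier_id,
               k_folds, seed)
}

#' @export
print.mi_classification_result <- function(x, ...) {
  cat(sprintf("<mi_classification_result> %s, %d-fold CV: %.2f%% correct\n",
              x$classifier_id, x$k_folds, x$success_rate))
  if (length(x$classes) > 2) {
    cat("confusion (row %):\n")
    print(round(x$confusion, 1))
  }
  invisible(x)
}

#' Serialize a classification result as a JSON run summary
#'
#' @param result an `mi_classification_result`.
#' @param path output JSON path.
#' @param config optional configuration list stored alongside.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(result, path, config = NULL) {
  jsonlite::write_json(
    list(classifier_id = result$classifier_id,
         k_folds = result$k_folds,
         seed = result$seed,
         success_rate = result$success_rate,
         per_fold_rates = result$per_fold_rates,
         classes = result$classes,
         confusion = as.data.frame(result$confusion),
         config = config),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
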