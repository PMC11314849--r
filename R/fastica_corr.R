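#' Build the observation matrix for independent-component extraction
#'
#' Appends the random reference row to the stacked trial matrix; the reference
#' is always the final row and every row carries a role tag.
#'
#' @param tm an `mi_trial_matrix`.
#' @param ref an `mi_reference_row` with matching sample count.
#' @return an `mi_observation_matrix`: list with `X` (rows x samples),
#'   `row_roles` (`"trial"`/`"reference"`), `sampling_rate_hz`, `class_label`.
#' @export
build_observation_matrix <- function(tm, ref) {
  stopifnot(inherits(tm, "mi_trial_matrix"), inherits(ref, "mi_reference_row"))
  if (length(ref$samples) != ncol(tm$rows)) {
    stop("reference length (", length(ref$samples),
         ") does not match trial sample count (", ncol(tm$rows), ")")
  }
  X <- rbind(tm$rows, reference = ref$samples)
  structure(list(X = X,
                 row_roles = c(rep("trial", nrow(tm$rows)), "reference"),
                 sampling_rate_hz = tm$sampling_rate_hz,
                 class_label = tm$class_label),
            class = "mi_observation_matrix")
}

# Contrast-function triples for the negentropy approximation: G (the
# contrast), g = G' (the update nonlinearity), dg = G'', and G's expectation
# under a standard Gaussian (for the negentropy proxy |E G(w'z) - E G(nu)|).
ica_nonlinearity <- function(id = c("logcosh", "gauss", "quartic")) {
  id <- match.arg(id)
  switch(id,
    logcosh = list(G = function(u) log(cosh(u)),
                   g = function(u) tanh(u),
                   dg = function(u) 1 - tanh(u)^2,
                   G_gauss = 0.37456704283),
    gauss = list(G = function(u) -exp(-u^2 / 2),
                 g = function(u) u * exp(-u^2 / 2),
                 dg = function(u) (1 - u^2) * exp(-u^2 / 2),
                 G_gauss = -1 / sqrt(2)),
    quartic = list(G = function(u) u^4 / 4,
                   g = function(u) u^3,
                   dg = function(u) 3 * u^2,
                   G_gauss = 3 / 4)
  )
}

#' Deflationary FastICA extraction
#'
#' Centers the observation rows, whitens them via the eigendecomposition of
#' the row covariance, then extracts `n_components` one at a time with the
#' fixed-point negentropy iteration
#' `w <- E[z g(w'z)] - E[g'(w'z)] w`, Gram-Schmidt-orthogonalizing each
#' update against the already-accepted components and renormalizing.
#' Convergence is declared when the direction change between successive
#' iterates falls below `tol`. Each deflation step runs `restarts` seeded
#' attempts and keeps the converged direction with the largest negentropy
#' proxy `|E G(w'z) - E G(nu)|` (projection pursuit: the one-unit iteration
#' converges to whichever local extremum its start happens to fall into, and
#' a single random start in many dimensions regularly lands on a spurious
#' finite-sample extremum instead of a genuine source, whose partial
#' projection deflation would then smear across later components). A
#' component is flagged unconverged - not fatal - only when every attempt
#' fails. Initial directions are drawn from a seeded Gaussian, so the
#' extraction is deterministic given `seed`.
#'
#' @param obs an `mi_observation_matrix`.
#' @param n_components number of components, `2 <= n_components <= rows`.
#' @param nonlinearity `"logcosh"` (default), `"gauss"` or `"quartic"`.
#' @param tol convergence tolerance on the direction change.
#' @param max_iter iteration cap per attempt.
#' @param restarts seeded attempts per component.
#' @param seed integer seed for the initial directions.
#' @return an `mi_component_set`: `components` (n x samples, unit variance),
#'   `unmixing` (n x rows, applies to centered data), `unmixing_whitened`
#'   (n x rows, orthonormal rows), `whitening` (rows x rows), `mean`,
#'   `nonlinearity_id`, `n_iterations`, `converged`, `component_seconds`.
#' @export
fastica_extract <- function(obs, n_components,
                            nonlinearity = c("logcosh", "gauss", "quartic"),
                            tol = 1e-4, max_iter = 200, restarts = 5L,
                            seed = 1L) {
  stopifnot(inherits(obs, "mi_observation_matrix"))
  nonlinearity <- match.arg(nonlinearity)
  X <- obs$X
  n_rows <- nrow(X)
  if (n_components < 2 || n_components > n_rows) {
    stop("`n_components` must be between 2 and the number of observation rows (",
         n_rows, " = trials x electrodes + reference); got ", n_components)
  }
  n_samples <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu

  # Whitening: eigendecomposition of the row covariance.
  C <- tcrossprod(Xc) / (n_samples - 1)
  eg <- eigen(C, symmetric = TRUE)
  deficient <- which(eg$values <= max(eg$values) * 1e-12)
  if (length(deficient)) {
    stop("rank-deficient whitening: covariance dimension(s) ",
         paste(deficient, collapse = ", "), " of ", n_rows,
         " carry (numerically) zero variance; remove duplicate or constant rows")
  }
  K <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  Z <- K %*% Xc

  nl <- ica_nonlinearity(nonlinearity)
  W <- matrix(0, n_components, n_rows)
  n_iterations <- integer(n_components)
  converged <- logical(n_components)
  comp_seconds <- numeric(n_components)
  restarts <- max(1L, as.integer(restarts))
  inits <- with_seed(seed,
                     matrix(rnorm(n_components * restarts * n_rows),
                            ncol = n_rows))

  deflate <- function(v, i) {
    if (i > 1) {
      v <- v - t(W[1:(i - 1), , drop = FALSE]) %*%
        (W[1:(i - 1), , drop = FALSE] %*% v)
    }
    drop(v)
  }
  for (i in seq_len(n_components)) {
    t0 <- proc.time()[["elapsed"]]
    iters_spent <- 0L
    best_w <- NULL
    best_contrast <- -Inf
    fallback_w <- NULL
    for (attempt in seq_len(restarts)) {
      w <- deflate(inits[(i - 1L) * restarts + attempt, ], i)
      w <- w / sqrt(sum(w^2))
      ok <- FALSE
      for (it in seq_len(max_iter)) {
        wz <- drop(crossprod(w, Z))             # 1 x samples projection
        w_new <- drop(Z %*% nl$g(wz)) / n_samples - mean(nl$dg(wz)) * w
        w_new <- deflate(w_new, i)
        w_new <- w_new / sqrt(sum(w_new^2))
        delta <- 1 - abs(sum(w_new * w))
        w <- w_new
        if (delta < tol) {
          ok <- TRUE
          break
        }
      }
      iters_spent <- iters_spent + it
      fallback_w <- w
      if (ok) {
        converged[i] <- TRUE
        contrast <- abs(mean(nl$G(drop(crossprod(w, Z)))) - nl$G_gauss)
        if (contrast > best_contrast) {
          best_contrast <- contrast
          best_w <- w
        }
      }
    }
    n_iterations[i] <- iters_spent
    W[i, ] <- if (is.null(best_w)) fallback_w else best_w
    comp_seconds[i] <- proc.time()[["elapsed"]] - t0
  }
  if (any(!converged)) {
    warning(sum(!converged), " component(s) did not converge within ",
            max_iter, " iterations")
  }

  components <- W %*% Z
  rownames(components) <- paste0("c", seq_len(n_components))
  structure(list(components = components,
                 unmixing = W %*% K,
                 unmixing_whitened = W,
                 whitening = K,
                 mean = mu,
                 nonlinearity_id = nonlinearity,
                 n_iterations = n_iterations,
                 converged = converged,
                 component_seconds = comp_seconds),
            class = "mi_component_set")
}

#' Pearson correlation coefficient with two-sided significance
#'
#' `r` is the standard Pearson coefficient; `p` is the two-sided significance
#' of `t = r * sqrt((N - 2) / (1 - r^2))` on `N - 2` degrees of freedom, with
#' the limit convention `p = 0` when `|r| = 1`.
#'
#' @param a,b numeric vectors of equal length `N >= 3`, each with nonzero
#'   variance.
#' @return named numeric `c(r = , p = )`.
#' @export
pearson_r_p <- function(a, b) {
  n <- length(a)
  if (length(b) != n) stop("`a` and `b` must have equal length")
  if (n < 3) stop("need at least 3 paired samples")
  am <- a - mean(a)
  bm <- b - mean(b)
  va <- sum(am^2)
  vb <- sum(bm^2)
  if (va == 0 || vb == 0) stop("zero variance input")
  r <- sum(am * bm) / sqrt(va * vb)
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
  }
  c(r = r, p = p)
}

#' Per-component correlation features
#'
#' Correlates the extraction input with every component, yielding one (r, p)
#' pair per component. The input of an extraction is a multi-row trial matrix
#' while each component is a single row, so a 1 x samples template stands in
#' for the input: by default the mean across the trial-role rows
#' (`template = "mean"`); `template = "per_trial"` instead correlates each
#' trial row with the component and averages r (and recomputes p from the
#' averaged r), as an alternative reading.
#'
#' @param obs the `mi_observation_matrix` the components were extracted from.
#' @param comps the `mi_component_set`.
#' @param class_label label attached to the features (defaults to the
#'   observation matrix's class).
#' @param template `"mean"` or `"per_trial"`.
#' @return data.frame with columns `component_index`, `r`, `p`, `class_label`.
#' @export
corr_features <- function(obs, comps, class_label = obs$class_label,
                          template = c("mean", "per_trial")) {
  stopifnot(inherits(obs, "mi_observation_matrix"),
            inherits(comps, "mi_component_set"))
  template <- match.arg(template)
  trials <- obs$X[obs$row_roles == "trial", , drop = FALSE]
  n <- nrow(comps$components)
  if (template == "mean") {
    tmpl <- colMeans(trials)
    rp <- t(vapply(seq_len(n), function(i) {
      pearson_r_p(tmpl, comps$components[i, ])
    }, c(r = 0, p = 0)))
  } else {
    nt <- ncol(trials)
    rp <- t(vapply(seq_len(n), function(i) {
      rs <- vapply(seq_len(nrow(trials)), function(j) {
        pearson_r_p(trials[j, ], comps$components[i, ])[["r"]]
      }, 0)
      r <- mean(rs)
      p <- if (abs(r) >= 1) 0 else {
        tt <- r * sqrt((nt - 2) / (1 - r^2))
        2 * pt(-abs(tt), df = nt - 2)
      }
      c(r = r, p = p)
    }, c(r = 0, p = 0)))
  }
  data.frame(component_index = seq_len(n), r = rp[, "r"], p = rp[, "p"],
             class_label = class_label, stringsAsFactors = FALSE)
}

#' Labeled FastICACorr feature dataset
#'
#' For each class and repetition: draw `n_trials` epochs of that class (a
#' seeded subsample when more are available), assemble the trial matrix over
#' `electrode_labels`, append a fresh seeded reference row, extract
#' `n_components` independent components, and correlate the trial template
#' with every component.
#'
#' Two observation units are supported. `unit = "pair"` (default) emits one
#' labeled 2-feature observation per (r, p) pair - `n_components` rows per
#' class per repetition. `unit = "run"` flattens the n pairs of one
#' extraction into a single observation whose columns are `absr_1..absr_n`
#' (|r|, sorted descending - component order and sign are arbitrary in ICA)
#' and `nlp_1..nlp_n` (the matching significance values as -log10 p, the
#' scale on which significance is compared; p is floored at 1e-300); one row
#' per class per repetition.
#'
#' @param epochs an `mi_epochs` object.
#' @param electrode_labels electrodes to stack.
#' @param classes class labels to include.
#' @param n_components components per extraction.
#' @param n_trials trials per extraction; classes with fewer epochs are an
#'   error naming the class.
#' @param repetitions extractions per class (each with a resampled trial
#'   subset and a fresh reference row).
#' @param unit `"pair"` or `"run"` (see Details).
#' @param nonlinearity,tol,max_iter passed to [fastica_extract()].
#' @param template passed to [corr_features()].
#' @param seed master seed; every subsample, reference row and extraction
#'   derives from it.
#' @return data.frame of labeled observations with a `class_label` column,
#'   a `repetition` column, and a `config` fingerprint attribute/column.
#' @export
build_fastica_feature_dataset <- function(epochs, electrode_labels, classes,
                                          n_components = 20, n_trials = 20,
                                          repetitions = 1,
                                          unit = c("pair", "run"),
                                          nonlinearity = "logcosh",
                                          tol = 1e-4, max_iter = 200,
                                          template = "mean",
                                          seed = 1L) {
  stopifnot(inherits(epochs, "mi_epochs"))
  unit <- match.arg(unit)
  by_class <- split(epochs$epochs,
                    vapply(epochs$epochs, `[[`, "", "class_label"))
  for (cl in classes) {
    avail <- length(by_class[[cl]])
    if (avail < n_trials) {
      stop(n_trials, " trials requested for class '", cl, "' but only ",
           avail, " available")
    }
  }
  cfg <- config_hash(list(electrode_labels, classes, n_components, n_trials,
                          repetitions, unit, nonlinearity, template, seed))
  seeds <- matrix(derive_seeds(seed, 2L * length(classes) * repetitions),
                  nrow = 2L)
  out <- list()
  k <- 0L
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    pool <- by_class[[cl]]
    for (rep_i in seq_len(repetitions)) {
      k <- k + 1L
      pick <- with_seed(seeds[1L, k],
                        sample(seq_along(pool), n_trials))
      sub <- structure(list(epochs = pool[pick],
                            sampling_rate_hz = epochs$sampling_rate_hz,
                            channel_labels = epochs$channel_labels,
                            epoch_length_samples = epochs$epoch_length_samples),
                       class = "mi_epochs")
      tm <- assemble_trial_matrix(sub, electrode_labels, cl)
      ref <- make_reference_row(ncol(tm$rows), seeds[2L, k])
      obs <- build_observation_matrix(tm, ref)
      comps <- fastica_extract(obs, n_components,
                               nonlinearity = nonlinearity,
                               tol = tol, max_iter = max_iter,
                               seed = seeds[2L, k])
      feats <- corr_features(obs, comps, class_label = cl,
                             template = template)
      if (unit == "pair") {
        feats$repetition <- rep_i
        feats$config <- cfg
        out[[k]] <- feats
      } else {
        ord <- order(abs(feats$r), decreasing = TRUE)
        row <- c(abs(feats$r)[ord], -log10(pmax(feats$p[ord], 1e-300)))
        names(row) <- c(paste0("absr_", seq_len(n_components)),
                        paste0("nlp_", seq_len(n_components)))
        out[[k]] <- data.frame(t(row), class_label = cl, repetition = rep_i,
                               config = cfg, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "config") <- cfg
  res
}

#' Write a feature table as delimited text
#'
#' @param features data.frame from [build_fastica_feature_dataset()] or
#'   [build_cssp_feature_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  data.table::fwrite(features, path, sep = "\t")
  invisible(path)
}
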