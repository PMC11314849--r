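# Laplacian sources mixed by a known matrix, as an identifiability fixture.
laplacian_mixture <- function(n_sources, n_samples, seed,
                              with_reference = TRUE) {
  set.seed(seed)
  S <- matrix(stats::rexp(n_sources * n_samples) *
                sample(c(-1, 1), n_sources * n_samples, replace = TRUE),
              nrow = n_sources)
  repeat {
    M <- matrix(stats::rnorm((n_sources + with_reference)^2),
                n_sources + with_reference)
    if (kappa(M) < 30) break
  }
  rows <- if (with_reference) rbind(S, stats::rnorm(n_samples)) else S
  X <- M %*% rows          # every observed row mixes all sources
  tm <- structure(list(rows = X,
                       electrode_labels = "C3",
                       trials_per_electrode = nrow(X),
                       class_label = "thumb",
                       sampling_rate_hz = 100),
                  class = "mi_trial_matrix")
  list(S = S, obs = build_observation_matrix(
    tm, make_reference_row(n_samples, seed + 1)))
}

test_that("observation matrices append exactly one tagged reference row", {
  ep <- epoch_recording(generate_recording(small_spec(trials_per_class = 4,
                                                      seed = 6)), 1)
  tm <- assemble_trial_matrix(ep, "C3", "thumb")
  obs <- build_observation_matrix(tm, make_reference_row(250, 3))
  expect_equal(dim(obs$X), c(5, 250))
  expect_equal(obs$row_roles, c(rep("trial", 4), "reference"))
  tm2 <- assemble_trial_matrix(ep, c("C3", "C4"), "thumb", n_trials = 4)
  # 20-row stacks supporting 20-component extraction get 21 rows
  tm20 <- tm2
  tm20$rows <- tm2$rows[rep(1:8, length.out = 20), ]
  expect_equal(nrow(build_observation_matrix(
    tm20, make_reference_row(250, 3))$X), 21)
  expect_error(build_observation_matrix(tm, make_reference_row(100, 3)),
               "does not match")
})

test_that("whitening and deflation honor their algebraic contracts", {
  mix <- laplacian_mixture(3, 4000, seed = 11)
  cs <- fastica_extract(mix$obs, 4, seed = 2)
  Z <- cs$whitening %*% (mix$obs$X - rowMeans(mix$obs$X))
  expect_lt(max(abs(tcrossprod(Z) / (ncol(Z) - 1) - diag(nrow(Z)))), 1e-8)
  WW <- cs$unmixing_whitened %*% t(cs$unmixing_whitened)
  expect_lt(max(abs(WW - diag(4))), 1e-6)
  expect_equal(nrow(cs$components), 4)
  expect_lt(max(abs(apply(cs$components, 1, stats::var) - 1)), 1e-6)
})

test_that("independent super-Gaussian sources are recovered by every contrast", {
  for (nl in c("logcosh", "gauss", "quartic")) {
    for (seed in c(1, 2, 3)) {
      mix <- laplacian_mixture(2, 3000, seed = 40 + seed)
      cs <- fastica_extract(mix$obs, 3, nonlinearity = nl, seed = seed)
      r <- abs(stats::cor(t(mix$S), t(cs$components)))
      expect_true(all(apply(r, 1, max) > 0.95),
                  label = sprintf("%s seed %d recovery", nl, seed))
    }
  }
})

test_that("extraction is deterministic and rejects impossible requests", {
  mix <- laplacian_mixture(2, 1500, seed = 7)
  a <- fastica_extract(mix$obs, 3, seed = 5)
  b <- fastica_extract(mix$obs, 3, seed = 5)
  expect_identical(a$components, b$components)
  expect_error(fastica_extract(mix$obs, 20, seed = 1), "observation rows")
  expect_error(fastica_extract(mix$obs, 1, seed = 1), "between 2")
  dup <- mix$obs
  dup$X[2, ] <- dup$X[1, ]
  expect_error(fastica_extract(dup, 2, seed = 1), "rank-deficient")
})

test_that("pearson_r_p matches closed forms and the definitional oracle", {
  expect_equal(unname(pearson_r_p(1:10, 1:10)), c(1, 0))
  # df = 1 closed form: t = 0.5*sqrt(1/0.75), p = 2*(1 - (1/2 + atan(t)/pi))
  rp <- pearson_r_p(c(1, 2, 3), c(1, 3, 2))
  expect_equal(rp[["r"]], 0.5, tolerance = 1e-12)
  expect_equal(rp[["p"]], 2 / 3, tolerance = 1e-12)
  # brute-force oracle with explicit sums, plus cor.test cross-check
  set.seed(99)
  for (i in 1:100) {
    a <- stats::rnorm(50)
    b <- stats::rnorm(50)
    n <- 50
    r_oracle <- (n * sum(a * b) - sum(a) * sum(b)) /
      sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
    t_oracle <- r_oracle * sqrt((n - 2) / (1 - r_oracle^2))
    p_oracle <- 2 * stats::pt(-abs(t_oracle), n - 2)
    rp <- pearson_r_p(a, b)
    expect_equal(rp[["r"]], r_oracle, tolerance = 1e-12)
    expect_equal(rp[["p"]], p_oracle, tolerance = 1e-12)
  }
  ct <- stats::cor.test(stats::rnorm(30), stats::rnorm(30))
  ab <- stats::rnorm(30); cd <- stats::rnorm(30)
  rp <- pearson_r_p(ab, cd)
  ct <- stats::cor.test(ab, cd)
  expect_equal(rp[["r"]], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(rp[["p"]], ct$p.value, tolerance = 1e-12)
  expect_error(pearson_r_p(rep(1, 10), 1:10), "zero variance")
  expect_error(pearson_r_p(1:2, 1:2), "at least 3")
})

test_that("pearson_r_p is symmetric and shift/scale invariant", {
  set.seed(4)
  a <- stats::rnorm(40)
  b <- stats::rnorm(40)
  expect_equal(pearson_r_p(a, b), pearson_r_p(b, a))
  expect_equal(pearson_r_p(a, b), pearson_r_p(2 * a + 3, b), tolerance = 1e-12)
})

test_that("corr_features yields one bounded (r, p) pair per component", {
  ep <- epoch_recording(generate_recording(small_spec(trials_per_class = 6,
                                                      seed = 14)), 1)
  tm <- assemble_trial_matrix(ep, "C4", "rest")
  obs <- build_observation_matrix(tm, make_reference_row(250, 2))
  cs <- suppressWarnings(fastica_extract(obs, 6, seed = 3))
  fe <- corr_features(obs, cs)
  expect_equal(nrow(fe), 6)
  expect_true(all(abs(fe$r) <= 1) && all(fe$p >= 0 & fe$p <= 1))
  # a component equal to the template correlates perfectly
  cs$components[1, ] <- colMeans(tm$rows)
  fe2 <- corr_features(obs, cs)
  expect_equal(fe2$r[1], 1)
  expect_equal(fe2$p[1], 0)
  # an orthogonal sinusoid is near-zero at N = 2000
  tmpl <- sin(2 * pi * 10 * (1:2000) / 1000)
  ortho <- sin(2 * pi * 21.3 * (1:2000) / 1000 + 1)
  expect_lt(abs(pearson_r_p(tmpl, ortho)[["r"]]), 0.05)
})

test_that("feature datasets conserve counts for both observation units", {
  ep <- epoch_recording(generate_recording(small_spec(trials_per_class = 8,
                                                      seed = 15)), 1)
  fp <- suppressWarnings(build_fastica_feature_dataset(
    ep, "C4", c("thumb", "rest"), n_components = 5, n_trials = 6,
    repetitions = 2, unit = "pair", seed = 5))
  expect_equal(nrow(fp), 5 * 2 * 2)
  expect_equal(names(fp)[1:4], c("component_index", "r", "p", "class_label"))
  fr <- suppressWarnings(build_fastica_feature_dataset(
    ep, "C4", c("thumb", "rest"), n_components = 5, n_trials = 6,
    repetitions = 3, unit = "run", seed = 5))
  expect_equal(nrow(fr), 2 * 3)
  expect_equal(sum(grepl("^absr_", names(fr))), 5)
  expect_equal(sum(grepl("^nlp_", names(fr))), 5)
  # sorted-profile canonicalization
  expect_true(all(apply(fr[, grep("^absr_", names(fr))], 1,
                        function(x) all(diff(x) <= 0))))
  expect_error(suppressWarnings(build_fastica_feature_dataset(
    ep, "C4", c("thumb", "rest"), n_components = 5, n_trials = 20, seed = 1)),
    "thumb.*only 8|only 8")
})

test_that("identical epochs for both classes leave features class-blind", {
  ep <- epoch_recording(generate_recording(small_spec(trials_per_class = 6,
                                                      seed = 44)), 1)
  # duplicate the rest epochs under both labels
  rests <- Filter(function(e) e$class_label == "rest", ep$epochs)
  fake <- lapply(rests, function(e) { e$class_label <- "thumb"; e })
  ep$epochs <- c(rests, fake)
  f <- suppressWarnings(build_fastica_feature_dataset(
    ep, "C4", c("thumb", "rest"), n_components = 4, n_trials = 6,
    repetitions = 4, unit = "run", seed = 9))
  cols <- grep("^(absr|nlp)_", names(f), value = TRUE)
  res <- crossval_evaluate(f[, cols], f$class_label, k_folds = 4, seed = 2)
  expect_lt(res$success_rate, 87.6)
  expect_gt(res$success_rate, 12.4)
})
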