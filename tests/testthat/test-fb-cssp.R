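test_that("the filter-bank plan matches the printed band layout", {
  fb <- build_filter_bank(100, 55)
  expect_equal(nrow(fb), 21)
  known <- fb[1:12, ]
  expect_equal(known$lo_hz, c(0.5, 4, 8, 12, 16, 20, 24, 28, 30, 34, 38, 42))
  expect_equal(known$hi_hz, c(4, 8, 12, 16, 20, 24, 28, 32, 34, 38, 42, 46))
  expect_equal(known$name[1:3], c("delta", "theta", "alpha"))
  expect_equal(sum(grepl("^sub-beta", known$name)), 5)
  expect_equal(sum(grepl("^sub-gamma", known$name)), 4)
  tiles <- fb[13:21, ]
  expect_equal(tiles$lo_hz, seq(55, 95, 5))
  expect_equal(tiles$hi_hz, seq(60, 100, 5))
  # limit at 46: known bands only; 80/65: three tiles
  expect_equal(nrow(build_filter_bank(46, 55)), 12)
  expect_equal(nrow(build_filter_bank(80, 65)), 15)
  expect_equal(build_filter_bank(80, 65)$lo_hz[13:15], c(65, 70, 75))
  expect_error(build_filter_bank(100, 60), "55 or 65")
  expect_warning(build_filter_bank(40, 55), "truncates")
  expect_error(build_filter_bank(40, 55, strict = TRUE), "truncates")
})

test_that("a pure tone concentrates in its band row", {
  fs <- 1000
  x <- sin(2 * pi * 10 * seq_len(4 * fs) / fs)
  fb <- build_filter_bank(100, 55)
  out <- apply_filter_bank(x, fb, fs)
  expect_equal(dim(out), c(21, 4 * fs))
  expect_equal(rownames(out), fb$name)
  r <- apply(out, 1, rms)
  alpha <- r[["alpha"]]
  non_adjacent <- setdiff(fb$name, c("alpha", "theta", "sub-beta-1"))
  expect_true(all(alpha > 10 * r[non_adjacent]))
  # zero in, zero out
  expect_equal(max(abs(apply_filter_bank(numeric(1000), fb, fs))), 0)
})

test_that("bands at or above Nyquist are dropped with a warning", {
  fb <- build_filter_bank(100, 55)
  expect_warning(out <- apply_filter_bank(stats::rnorm(500), fb, 160),
                 "Nyquist")
  expect_equal(nrow(out), sum(fb$hi_hz < 80))
  expect_error(apply_filter_bank(stats::rnorm(500), fb, 160, strict = TRUE),
               "Nyquist")
})

test_that("the two-band comparator solves the closed-form instance", {
  set.seed(1)
  A <- diag(c(2, 1)) %*% matrix(stats::rnorm(2 * 20000), 2)   # cov diag(4,1)
  B <- diag(c(1, 2)) %*% matrix(stats::rnorm(2 * 20000), 2)   # cov diag(1,4)
  rownames(A) <- rownames(B) <- c("b1", "b2")
  model <- cssp_fit(A, B, 1)
  expect_equal(model$eigenvalues[1], 0.8, tolerance = 0.02)
  w <- model$projection[1, ]
  angle <- acos(abs(w[1]) / sqrt(sum(w^2))) * 180 / pi
  expect_lt(angle, 2)
  expect_error(cssp_fit(A, B, 2), "floor")
})

test_that("the top filter matches a brute-force direction search", {
  set.seed(7)
  M1 <- matrix(stats::rnorm(4), 2)
  M2 <- matrix(stats::rnorm(4), 2)
  A <- M1 %*% matrix(stats::rnorm(2 * 30000), 2)
  B <- M2 %*% matrix(stats::rnorm(2 * 30000), 2)
  model <- cssp_fit(A, B, 1)
  Ca <- tcrossprod(A - rowMeans(A)) / (ncol(A) - 1)
  Cb <- tcrossprod(B - rowMeans(B)) / (ncol(B) - 1)
  Ca <- Ca / sum(diag(Ca)); Cb <- Cb / sum(diag(Cb))
  theta <- (seq_len(3600) - 1) / 3600 * pi
  ratio <- vapply(theta, function(th) {
    w <- c(cos(th), sin(th))
    drop(w %*% Ca %*% w / (w %*% (Ca + Cb) %*% w))
  }, 0)
  w_best <- c(cos(theta[which.max(ratio)]), sin(theta[which.max(ratio)]))
  w_fit <- model$projection[1, ] / sqrt(sum(model$projection[1, ]^2))
  angle <- acos(pmin(1, abs(sum(w_best * w_fit)))) * 180 / pi
  expect_lt(angle, 0.1)
  expect_equal(model$eigenvalues[1], max(ratio), tolerance = 1e-4)
})

test_that("identical class distributions give eigenvalues near one half", {
  set.seed(3)
  M <- matrix(stats::rnorm(16), 4)
  A <- M %*% matrix(stats::rnorm(4 * 10000), 4)
  B <- M %*% matrix(stats::rnorm(4 * 10000), 4)
  model <- cssp_fit(A, B, 2)
  expect_true(all(abs(model$eigenvalues - 0.5) < 0.05))
})

test_that("swapping classes mirrors the eigenvalue spectrum", {
  set.seed(8)
  A <- matrix(stats::rnorm(3 * 5000), 3) * c(3, 1, 0.5)
  B <- matrix(stats::rnorm(3 * 5000), 3)
  m_ab <- cssp_fit(A, B, 1)
  m_ba <- cssp_fit(B, A, 1)
  expect_equal(sort(m_ab$eigenvalues), sort(1 - m_ba$eigenvalues),
               tolerance = 1e-9)
  # joint scaling leaves the spectrum unchanged
  m_scaled <- cssp_fit(7 * A, 7 * B, 1)
  expect_equal(m_ab$eigenvalues, m_scaled$eigenvalues, tolerance = 1e-9)
})

test_that("cssp_features pairs f_a and f_b of the right length", {
  fs <- 1000
  fb <- build_filter_bank(100, 55)
  set.seed(5)
  x <- stats::rnorm(3000)
  A <- apply_filter_bank(x, fb, fs)
  feats <- cssp_features(cssp_fit(A, A, 1), A, A)
  expect_length(feats$f_a, 21)
  expect_length(feats$f_b, 21)
  expect_equal(feats$f_a, feats$f_b, tolerance = 1e-9)
})

test_that("feature separation grows with the depth of the suppression", {
  sep <- vapply(c(0.2, 0.5, 0.8), function(d) {
    spec <- small_spec(erd_depth = d, trials_per_class = 6, seed = 17,
                       sampling_rate_hz = 250)
    ep <- epoch_recording(generate_recording(spec), 1)
    fb <- suppressWarnings(build_filter_bank(45, 55))  # 45 Hz limit on purpose
    cls <- vapply(ep$epochs, `[[`, "", "class_label")
    stack <- function(lbl) {
      do.call(cbind, lapply(ep$epochs[cls == lbl],
                            function(e) apply_filter_bank(e$data["C4", ], fb, 250)))
    }
    A <- stack("thumb"); B <- stack("rest")
    feats <- cssp_features(cssp_fit(A, B, 1), A, B)
    sqrt(sum((feats$f_a - feats$f_b)^2))
  }, 0)
  expect_true(all(diff(sep) > 0))
})

test_that("the comparator dataset is fold-aware and two-class only", {
  spec <- small_spec(trials_per_class = 10, seed = 23)
  ep <- epoch_recording(generate_recording(spec), 1)
  expect_error(build_cssp_feature_dataset(ep, "C4",
                                          c("thumb", "rest", "index")),
               "exactly two classes")
  fb45 <- suppressWarnings(build_filter_bank(45, 55))
  f <- build_cssp_feature_dataset(ep, "C4", c("thumb", "rest"), fb = fb45,
                                  n_trials = 10, k_folds = 5, seed = 2)
  # per fold-assembly: all trials, tagged train or test
  expect_equal(nrow(f), 5 * 20)
  expect_equal(sum(f$role == "test"), 20)
  per_fold <- table(f$fold[f$role == "test"])
  expect_true(all(per_fold == 4))
  # m = 1 feature dimensionality equals the band count
  expect_equal(sum(grepl("^f_", names(f))), nrow(fb45))
  res <- crossval_evaluate_cssp(f, seed = 3)
  expect_s3_class(res, "mi_classification_result")
  expect_gte(res$success_rate, 0)
})
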