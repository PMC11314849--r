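test_that("spec validation rejects malformed inputs", {
  expect_error(small_spec(classes = character()), "nonempty")
  expect_error(small_spec(classes = c("thumb", "thumb")), "duplicate")
  expect_error(small_spec(classes = c("thumb", "palm")), "subset")
  expect_error(small_spec(erd_band_hz = c(8, 200)), "erd_band_hz")
  expect_error(small_spec(erd_depth = 1), "erd_depth")
  expect_error(small_spec(motor_channels = "C9"), "motor_channels")
  expect_error(small_spec(rest_epoch_s_range = c(2, 1)), "rest_epoch_s_range")
  expect_error(small_spec(line_freq_hz = 55), "50 or 60")
  expect_error(small_spec(channel_labels = c("C3", "C3", "C4", "P3", "Pz", "P4")),
               "duplicate")
})

test_that("generated recordings have the configured shape and event plan", {
  spec <- synthetic_spec(n_channels = 22, sampling_rate_hz = 1000,
                         trials_per_class = 2, seed = 5)
  rec <- generate_recording(spec)
  expect_equal(nrow(rec$data), 22)
  expect_equal(rec$sampling_rate_hz, 1000)
  expect_equal(nrow(rec$events), 2 * 6)
  expect_equal(sort(unique(rec$events$class_label)), sort(spec$classes))
  expect_equal(as.vector(table(rec$events$class_label)), rep(2L, 6))
  # events tile the recording exactly
  ev <- rec$events
  expect_true(all(diff(ev$onset_sample) == head(ev$n_samples, -1)))
  expect_equal(ev$onset_sample[nrow(ev)] + ev$n_samples[nrow(ev)] - 1L,
               ncol(rec$data))
})

test_that("identical spec and seed give bit-identical recordings", {
  spec <- small_spec(seed = 77)
  r1 <- generate_recording(spec)
  r2 <- generate_recording(spec)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)
  r3 <- generate_recording(small_spec(seed = 78))
  expect_false(identical(r1$data, r3$data))
})

test_that("movement epochs lose the configured fraction of band power", {
  spec <- small_spec(erd_depth = 0.5, trials_per_class = 12, seed = 9,
                     sampling_rate_hz = 500, passband_hz = c(0.53, 100))
  rec <- generate_recording(spec)
  ep <- epoch_recording(rec, 1)
  cls <- vapply(ep$epochs, `[[`, "", "class_label")
  mv <- mean(vapply(ep$epochs[cls == "thumb"],
                    function(e) band_power(e$data["C4", ], 500, 8, 12), 0))
  rs <- mean(vapply(ep$epochs[cls == "rest"],
                    function(e) band_power(e$data["C4", ], 500, 8, 12), 0))
  expect_lt(abs(mv / rs - 0.5), 0.15 * 0.5)
  # non-motor channels see no class difference in the band
  mvn <- mean(vapply(ep$epochs[cls == "thumb"],
                     function(e) band_power(e$data["Pz", ], 500, 8, 12), 0))
  rsn <- mean(vapply(ep$epochs[cls == "rest"],
                     function(e) band_power(e$data["Pz", ], 500, 8, 12), 0))
  expect_lt(abs(mvn / rsn - 1), 0.5)
})

test_that("band-power suppression deepens monotonically with erd_depth", {
  ratio <- vapply(c(0.2, 0.5, 0.8), function(d) {
    rec <- generate_recording(small_spec(erd_depth = d, trials_per_class = 10,
                                         seed = 31))
    ep <- epoch_recording(rec, 1)
    cls <- vapply(ep$epochs, `[[`, "", "class_label")
    mv <- mean(vapply(ep$epochs[cls == "thumb"],
                      function(e) band_power(e$data["C4", ], 250, 8, 12), 0))
    rs <- mean(vapply(ep$epochs[cls == "rest"],
                      function(e) band_power(e$data["C4", ], 250, 8, 12), 0))
    mv / rs
  }, 0)
  expect_true(all(diff(ratio) < 0))
})

test_that("zero erd_depth leaves movement and rest indistinguishable", {
  rec <- generate_recording(small_spec(erd_depth = 0, trials_per_class = 50,
                                       seed = 13))
  ep <- epoch_recording(rec, 1)
  cls <- vapply(ep$epochs, `[[`, "", "class_label")
  bp <- vapply(ep$epochs, function(e) band_power(e$data["C4", ], 250, 8, 12), 0)
  expect_gt(stats::t.test(bp[cls == "thumb"], bp[cls == "rest"])$p.value, 0.01)
})

test_that("mains contamination appears on every channel when configured", {
  spec <- small_spec(line_freq_hz = 50, line_amplitude = 2,
                     passband_hz = c(0.53, 45), sampling_rate_hz = 250,
                     trials_per_class = 4, seed = 3)
  rec <- generate_recording(spec)
  p50 <- vapply(seq_len(nrow(rec$data)),
                function(i) band_power(rec$data[i, 1:2000], 250, 49, 51), 0)
  pno <- vapply(seq_len(nrow(rec$data)),
                function(i) band_power(rec$data[i, 1:2000], 250, 30, 32), 0)
  expect_true(all(p50 > 10 * pno))
})

test_that("degenerate epoch sizing is rejected", {
  expect_error(generate_recording(small_spec(movement_epoch_s = 0.001)),
               "do not fit|fit")
})
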