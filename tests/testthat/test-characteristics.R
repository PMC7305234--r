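test_that("spindle density is exact arithmetic", {
  expect_equal(spindle_density(24, 6 * 60), 4)
  expect_equal(spindle_density(0, 600), 0)
  expect_equal(spindle_density(14, 345), 14 / (345 / 60), tolerance = 1e-12)
  expect_equal(spindle_density(14, 345), 2.434783, tolerance = 1e-6)
  expect_error(spindle_density(3, 0), "positive")
  # linear in count, inverse-linear in time
  expect_equal(spindle_density(20, 300), 2 * spindle_density(10, 300))
  expect_equal(spindle_density(10, 600), spindle_density(10, 300) / 2)
})

test_that("peak-to-peak amplitude recovers an in-band sinusoid and rejects out-of-band power", {
  t <- (0:1999) / 100
  x <- eeg_signal(15 * sin(2 * pi * 13 * t), 100) # 30 uV p2p
  a <- event_amplitude(x, onset_s = 8, duration_s = 1)
  expect_equal(a, 30, tolerance = 0.05 * 30)
  # strong 5 Hz component is filtered out by the 11-16 Hz band
  y <- eeg_signal(15 * sin(2 * pi * 13 * t) + 50 * sin(2 * pi * 5 * t), 100)
  a2 <- event_amplitude(y, onset_s = 8, duration_s = 1)
  expect_equal(a2, 30, tolerance = 0.05 * 30)
  # zero signal
  z <- eeg_signal(rep(0, 2000), 100)
  expect_equal(event_amplitude(z, 8, 1), 0)
  expect_error(event_amplitude(x, 8, 0.005), "too short")
})

test_that("dominant frequency lands within the zero-padded FFT resolution", {
  t <- (0:1999) / 100
  x <- eeg_signal(15 * sin(2 * pi * 13 * t), 100)
  f <- event_frequency(x, onset_s = 8, duration_s = 1)
  expect_equal(f, 13, tolerance = 0.2) # resolution 1/(1+5) Hz
  # the larger of two in-band components wins
  m <- eeg_signal(
    3 * sin(2 * pi * 11.5 * t) + 12 * sin(2 * pi * 14.5 * t), 100
  )
  f2 <- event_frequency(m, onset_s = 8, duration_s = 1)
  expect_equal(f2, 14.5, tolerance = 0.2)
  # DC-only event: no in-band energy -> flagged missing
  dc <- eeg_signal(rep(3, 2000), 100)
  expect_true(is.na(event_frequency(dc, 8, 1)))
})

test_that("subject metrics aggregate per-event measures and density", {
  t <- (0:(115 * 100 - 1)) / 100
  x <- 15 * sin(2 * pi * 13 * t) * 0 # quiet background
  ev <- tibble::tibble(onset_s = c(10, 50), duration_s = c(0.6, 1.0))
  for (k in 1:2) {
    idx <- (ev$onset_s[k] * 100):((ev$onset_s[k] + ev$duration_s[k]) * 100 - 1) + 1
    x[idx] <- 15 * sin(2 * pi * 13 * t[idx])
  }
  sig <- eeg_signal(x, 100)
  grid <- build_epoch_grid(0)
  m <- subject_metrics(ev, sig, grid)
  expect_equal(m$mean_duration_s, 0.8)
  expect_equal(m$density_spm, 2 / (115 / 60), tolerance = 1e-12)
  expect_equal(m$dominant_freq_hz, 13, tolerance = 0.2)
  expect_equal(m$mean_amplitude_uv, 30, tolerance = 3)
  # single event: metrics equal that event's values
  m1 <- subject_metrics(ev[2, ], sig, grid)
  expect_equal(m1$mean_duration_s, 1.0)
  expect_identical(m1$n_events, 1L)
  # no events: flagged missing
  m0 <- subject_metrics(ev[0, ], sig, grid)
  expect_equal(m0$density_spm, 0)
  expect_true(is.na(m0$mean_duration_s))
})

test_that("characteristic correlation is 1 for affine relations and near 0 for noise", {
  mk <- function(v, id = seq_along(v)) {
    tibble::tibble(
      subject_id = sprintf("s%d", id), density_spm = v,
      mean_duration_s = v / 10, mean_amplitude_uv = v * 3, dominant_freq_hz = 13 + v / 50
    )
  }
  a <- mk(c(2, 4, 6, 8, 10))
  cc <- characteristic_correlation(a, a)
  expect_equal(cc$r_squared, rep(1, 4))
  b <- mk(2 * c(2, 4, 6, 8, 10) + 1)
  cc2 <- characteristic_correlation(a, b)
  expect_equal(cc2$r_squared, rep(1, 4), tolerance = 1e-12)
  set.seed(50)
  r1 <- mk(rnorm(100))
  r2 <- mk(rnorm(100))
  cc3 <- characteristic_correlation(r1, r2)
  expect_true(all(cc3$r_squared < 0.1))
  # zero variance flagged undefined
  flat <- mk(rep(3, 5))
  cc4 <- characteristic_correlation(a, flat)
  expect_true(all(is.na(cc4$r_squared)))
  expect_error(characteristic_correlation(a[1:2, ], a[1:2, ]), "at least 3")
})

test_that("group comparison reports Mann-Whitney p-values, medians and stars", {
  mk <- function(v) {
    tibble::tibble(
      density_spm = v, mean_duration_s = v, mean_amplitude_uv = v,
      dominant_freq_hz = v
    )
  }
  same <- mk(c(1:10, 1:10))
  cg <- compare_groups(same, rep(c("a", "b"), each = 10))
  expect_true(all(cg$p_value > 0.9))
  expect_true(all(cg$stars == ""))
  expect_equal(cg$median_a, rep(median(1:10), 4))

  set.seed(51)
  g1 <- rnorm(50)
  g2 <- rnorm(50) + 3
  sh <- compare_groups(mk(c(g1, g2)), rep(c("a", "b"), each = 50))
  expect_true(all(sh$p_value < 0.001))
  expect_true(all(sh$stars == "***"))
  expect_equal(sh$median_b[1], median(g2))

  expect_error(compare_groups(mk(1:5), rep("a", 5)), "two non-empty groups")
})

test_that("frequency histogram bins 0.25 Hz over the sigma search range", {
  h1 <- frequency_histogram(13.1)
  expect_identical(sum(h1$count), 1L)
  expect_true(h1$bin_lo[h1$count == 1] == 13.0)
  h0 <- frequency_histogram(numeric(0))
  expect_identical(nrow(h0), 0L)
  set.seed(52)
  cohort <- rnorm(200, 13.3, 0.4)
  h <- frequency_histogram(cohort)
  mode_bin <- h$bin_mid[which.max(h$count)]
  expect_lt(abs(mode_bin - 13.3), 0.25 + 0.125)
})
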