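fs <- 100
t10 <- (0:999) / fs

test_that("high-pass removes DC and passes in-band tones", {
  dc <- make_recording(rep(2.5, 2000))
  out <- apply_filter(dc, filter_spec("highpass", 1))
  core <- out$channels[501:1500, 1]
  expect_lt(max(abs(core)), 2.5 * 1e-6)

  tone10 <- make_recording(sin(2 * pi * 10 * t10))
  hp <- apply_filter(tone10, filter_spec("highpass", 1))
  lp <- suppressWarnings(apply_filter(hp, filter_spec("lowpass", 50)))
  amp <- sine_amplitude(lp$channels[201:800, 1])
  gain <- butter_zero_phase_gain(10, 1, fs, 4, "high") *
    butter_zero_phase_gain(10, 49.5, fs, 4, "low")
  expect_lt(abs(amp - gain), 0.05)
  expect_gt(amp, 0.95)
})

test_that("out-of-band tone is strongly attenuated per the response oracle", {
  tone02 <- make_recording(sin(2 * pi * 0.2 * (0:2999) / fs))
  out <- apply_filter(tone02, filter_spec("highpass", 1))
  amp <- sine_amplitude(out$channels[501:2500, 1])
  gain <- butter_zero_phase_gain(0.2, 1, fs, 4, "high")
  expect_lt(amp, 0.10)
  expect_lt(abs(amp - gain), 0.02)
})

test_that("a cutoff at Nyquist is clamped with a warning", {
  rec <- make_recording(rnorm(500))
  expect_warning(apply_filter(rec, filter_spec("lowpass", 50)), "clamped")
  expect_warning(apply_filter(rec, filter_spec("lowpass", 60)), "clamped")
})

test_that("filtering is linear and zero-phase", {
  set.seed(42)
  x <- rnorm(1000)
  y <- rnorm(1000)
  spec <- filter_spec("highpass", 1)
  fx <- apply_filter(make_recording(x), spec)$channels[, 1]
  fy <- apply_filter(make_recording(y), spec)$channels[, 1]
  fxy <- apply_filter(make_recording(2 * x - 3 * y), spec)$channels[, 1]
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-8)

  # band-limited input: the cross-correlation peak must sit at lag 0
  bl <- apply_filter(make_recording(rnorm(2000)),
                     filter_spec("lowpass", 10))$channels[, 1]
  flt <- apply_filter(make_recording(bl), filter_spec("highpass", 1))$channels[, 1]
  cc <- stats::ccf(bl, flt, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(abs(cc$acf)), 1, 1], 0)
})

test_that("anomaly threshold is mean + k sd and flags exactly the spike", {
  x <- c(rep(0, 99), 100)
  rec <- make_recording(x)
  mask <- detect_anomalies(rec, k = 2)
  expect_equal(unname(mask$threshold), 1 + 2 * sqrt(99), tolerance = 1e-12)
  expect_equal(which(mask$flags[, 1]), 100L)

  # constant channel: sd 0, nothing strictly exceeds its own mean
  expect_equal(sum(detect_anomalies(make_recording(rep(3, 50)))$flags), 0L)
  # k large: no flags
  expect_equal(sum(detect_anomalies(rec, k = 1e9)$flags), 0L)
  # flags invariant under adding a constant
  shifted <- detect_anomalies(make_recording(x + 123.4), k = 2)
  expect_identical(shifted$flags, mask$flags)
})

test_that("anomaly removal interpolates or drops as requested", {
  x <- c(1, 1, 1, 3, 50, 1, 1, 1, 1, 1)
  rec <- make_recording(x)
  mask <- detect_anomalies(rec, k = 2)
  expect_equal(which(mask$flags[, 1]), 5L)
  fixed <- remove_anomalies(rec, mask, "interpolate")
  expect_equal(fixed$channels[5, 1], (3 + 1) / 2,
               ignore_attr = TRUE)  # linear midpoint
  expect_equal(fixed$channels[-5, 1], x[-5], ignore_attr = TRUE)

  dropped <- remove_anomalies(rec, mask, "drop")
  expect_s3_class(dropped, "data.frame")
  expect_equal(nrow(dropped), 9L)

  # zero flags: identity
  none <- detect_anomalies(rec, k = 1e9)
  expect_equal(remove_anomalies(rec, none, "interpolate")$channels,
               rec$channels)
})

test_that("baseline correction removes slow trend, preserves 5 Hz", {
  ramp <- make_recording(seq(0, 10, length.out = 3000))
  out <- baseline_correct(ramp)
  expect_lt(abs(mean(out$channels[501:2500, 1])), 1e-3 * 10)

  tone5 <- make_recording(sin(2 * pi * 5 * (0:2999) / fs))
  kept <- baseline_correct(tone5)
  expect_lt(abs(sine_amplitude(kept$channels[501:2500, 1]) - 1), 0.05)

  zero <- baseline_correct(make_recording(rep(0, 1000)))
  expect_equal(max(abs(zero$channels)), 0)
})

test_that("min-max normalisation maps to [0,1] and is idempotent", {
  rec <- make_recording(c(-2, 0, 2))
  out <- minmax_normalize(rec)
  expect_equal(out$channels[, 1], c(0, 0.5, 1))
  expect_equal(minmax_normalize(out)$channels, out$channels)

  const <- minmax_normalize(make_recording(rep(7, 10)))
  expect_equal(const$channels[, 1], rep(0, 10))

  set.seed(1)
  r <- minmax_normalize(make_recording(rnorm(100)))
  expect_equal(range(r$channels), c(0, 1))
})

test_that("the full preprocessing chain bounds output and tames spikes", {
  cfg <- synthetic_config(duration_s = 60, seed = 13L,
                          artifact_rate_per_min = 4)
  rec <- generate_recording(cfg, "normotensive")
  out <- preprocess_recording(rec)
  expect_true(all(out$channels >= 0 & out$channels <= 1))
  expect_equal(nrow(out$channels), nrow(rec$channels))
  stages <- attr(out, "stages")
  expect_equal(vapply(stages, `[[`, character(1), "stage"),
               c("highpass", "lowpass", "anomaly", "baseline", "minmax"))

  expect_gt(stages[[3]]$n_flagged, 0)  # the artifacts were actually flagged

  expect_error(preprocess_recording(rec, anomaly_mode = "drop"),
               "uniform sampling")
})

test_that("an injected spike no longer exceeds mean + 2 sd after the chain", {
  cfg <- synthetic_config(duration_s = 60, seed = 17L,
                          artifact_rate_per_min = 0)
  rec <- generate_recording(cfg, "normotensive")
  spike_idx <- 3000:3005
  rec$channels[spike_idx, ] <- rec$channels[spike_idx, ] + 40
  out <- preprocess_recording(rec)
  mu <- colMeans(out$channels)
  sdv <- sqrt(colMeans(sweep(out$channels, 2, mu)^2))
  for (ch in seq_len(ncol(out$channels)))
    expect_true(all(out$channels[spike_idx, ch] <= mu[ch] + 2 * sdv[ch]))
})
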