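# Peak detection, settling time and the six-feature extractor.

test_that("monotone series yield no peaks", {
  pk <- find_peaks(seq_len(1000) / 10, 5000)
  expect_equal(nrow(pk$maxima), 0)
  expect_equal(nrow(pk$minima), 0)
})

test_that("1 Hz sinusoid peaks fall at the analytic extrema", {
  fs <- 5000
  tt <- (0:(4 * fs - 1)) / fs
  pk <- find_peaks(sin(2 * pi * tt), fs)
  expect_equal(nrow(pk$maxima), 4)
  expect_equal(pk$maxima$time, c(0.25, 1.25, 2.25, 3.25),
               tolerance = 1 / fs + 1e-9)
  expect_equal(pk$minima$time, c(0.75, 1.75, 2.75, 3.75),
               tolerance = 1 / fs + 1e-9)
})

test_that("damped sinusoid maxima match a dense-grid argmax oracle", {
  fs <- 5000
  A <- 50; f <- 1.25; tau <- 0.8
  tt <- (0:(4 * fs - 1)) / fs
  x <- A * exp(-tt / tau) * sin(2 * pi * f * tt)
  pk <- find_peaks(x, fs)

  dense <- seq(0, 4, by = 1e-5)
  xd <- A * exp(-dense / tau) * sin(2 * pi * f * dense)
  oracle_times <- vapply(seq_len(nrow(pk$maxima)), function(k) {
    lo <- (k - 1) / f; hi <- lo + 0.5 / f
    seg <- dense >= lo & dense <= hi
    dense[seg][which.max(xd[seg])]
  }, numeric(1))
  expect_equal(pk$maxima$time, oracle_times, tolerance = 1 / fs + 1e-9)
})

test_that("spacing rule keeps the larger peak of a close pair", {
  fs <- 1000
  x <- numeric(1000)
  x[200] <- 1; x[230] <- 0.6   # 30 ms apart
  x <- lowpass_filter(x, fs, cutoff = 200)  # smooth into genuine local maxima
  pk <- find_peaks(x, fs, min_distance = 0.1, min_prominence = 0.01)
  expect_equal(nrow(pk$maxima), 1)
  expect_equal(pk$maxima$index, which.max(x))
})

test_that("settling time handles impulse, uniform and damped cases", {
  fs <- 5000
  imp <- c(1, numeric(4 * fs - 1))
  expect_equal(settling_time(imp, fs), 0)

  const <- rep(2, 4 * fs)
  expect_equal(settling_time(const, fs), 0.97 * 4, tolerance = 1 / fs + 1e-9)

  tau <- 0.8
  tt <- (0:(4 * fs - 1)) / fs
  x <- 50 * exp(-tt / tau) * sin(2 * pi * 1.25 * tt)
  # oracle: cumulative energy crossing on a 10x denser grid
  dense <- seq(0, 4, by = 1 / (10 * fs))
  xd <- 50 * exp(-dense / tau) * sin(2 * pi * 1.25 * dense)
  ed <- cumsum(xd^2)
  t_oracle <- dense[which(ed >= 0.97 * ed[length(ed)])[1]]
  expect_equal(settling_time(x, fs), t_oracle, tolerance = 2e-3)

  expect_error(settling_time(numeric(100), fs),
               class = "reflexquant_degenerate_signal_error")
})

test_that("features of a noiseless damped sinusoid match closed forms", {
  p <- oracle_params(A = 50, f = 1.25, tau = 0.8, gain_v = 0.08)
  cfg <- pipeline_config()
  tr <- preprocess_recording(damped_reflex_waveform(p, seed = 1), cfg)
  fv <- extract_features(tr, cfg)
  fs <- tr$sample_rate
  w <- 2 * pi * p$f

  # max-to-min interval: half a period; first-to-third peaks: two periods
  expect_equal(fv$delta_t1_ms, 1000 / (2 * p$f), tolerance = 1000 / fs + 1e-6)
  expect_equal(fv$delta_t2_s, 2 / p$f, tolerance = 2 / fs + 1e-9)

  # peak ratio: evaluate the waveform at the detected peak times (oracle)
  expect_equal(fv$ratio_13, exp(-fv$delta_t2_s / p$tau), tolerance = 0.01)

  # peak-to-peak span from the closed-form first peak/trough amplitudes
  tp <- atan(w * p$tau) / w
  span <- p$A * (exp(-tp / p$tau) * sin(w * tp) +
                   exp(-(tp + pi / w) / p$tau) * abs(sin(w * (tp + pi / w))))
  expect_equal(fv$delta_a, span, tolerance = 0.005 * span)

  # peak velocity ~ gain * A * w at onset
  expect_equal(fv$vmax, p$gain_v * p$A * w, tolerance = 0.01 * p$gain_v * p$A * w)
})

test_that("peak-ratio equals exp(-dt2/tau) within 1% for tau >= 0.3", {
  fs <- 5000
  tt <- (0:(4 * fs - 1)) / fs
  cfg <- pipeline_config()
  for (tau in c(0.3, 0.5, 0.8, 1.2)) {
    x <- 40 * exp(-tt / tau) * sin(2 * pi * 1.25 * tt)
    fv <- extract_features(as_trimmed(x, velocity = abs(x)), cfg)
    expect_equal(fv$ratio_13, exp(-fv$delta_t2_s / tau),
                 tolerance = 0.01, label = sprintf("tau = %g", tau))
  }
})

test_that("scaling the angle scales delta_a and nothing else", {
  fs <- 5000
  tt <- (0:(4 * fs - 1)) / fs
  x <- 20 * exp(-tt / 0.7) * sin(2 * pi * 1.3 * tt)
  cfg <- pipeline_config()
  f1 <- extract_features(as_trimmed(x, abs(x)), cfg)
  f2 <- extract_features(as_trimmed(3 * x, abs(x)), cfg)
  expect_equal(f2$delta_a, 3 * f1$delta_a, tolerance = 1e-9)
  for (feat in c("ratio_13", "delta_t1_ms", "delta_t2_s", "ts_s")) {
    expect_equal(f2[[feat]], f1[[feat]], tolerance = 1e-9, label = feat)
  }
})

test_that("features are invariant to the impact time (time-shift)", {
  cfg <- pipeline_config()
  p1 <- oracle_params(); p1$impact_time <- 0.3
  p2 <- oracle_params(); p2$impact_time <- 0.7
  f1 <- extract_features(preprocess_recording(
    damped_reflex_waveform(p1, duration = 4.8), cfg), cfg)
  f2 <- extract_features(preprocess_recording(
    damped_reflex_waveform(p2, duration = 4.8), cfg), cfg)
  for (feat in c("delta_a", "ratio_13", "ts_s", "vmax")) {
    expect_equal(f2[[feat]], f1[[feat]], tolerance = 1e-6, label = feat)
  }
  expect_equal(f2$delta_t1_ms, f1$delta_t1_ms, tolerance = 0.2 + 1e-9)
  expect_equal(f2$delta_t2_s, f1$delta_t2_s, tolerance = 2e-4 + 1e-9)
})

test_that("degenerate traces impute or raise per configuration", {
  fs <- 5000
  hump <- c(2 * sin(pi * (0:999) / 1000), numeric(4 * fs - 1000))

  imputing <- pipeline_config(impute_degenerate = TRUE)
  fv <- extract_features(as_trimmed(hump), imputing)
  expect_true(fv$degenerate)
  expect_equal(fv$ratio_13, 1)
  expect_equal(fv$delta_t2_s, 0)

  strict <- pipeline_config(impute_degenerate = FALSE)
  expect_error(extract_features(as_trimmed(hump), strict),
               class = "reflexquant_feature_error")

  expect_error(extract_features(as_trimmed(numeric(1000)), imputing),
               class = "reflexquant_degenerate_signal_error")
})
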