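# Damped-oscillation generator: closed forms, determinism, dataset assembly.

test_that("zero amplitude and zero noise give all-zero channels", {
  p <- generator_params(A = 0, sigma_angle = 0, sigma_velocity = 0,
                        baseline_amp = 0)
  rec <- damped_reflex_waveform(p, duration = 1, seed = 1)
  expect_true(all(rec$angle == 0))
  expect_true(all(rec$velocity == 0))
  expect_gt(max(rec$impact), 0)  # the impact pulse is still emitted
})

test_that("noise-free angle equals the closed-form damped sinusoid", {
  p <- oracle_params()
  rec <- damped_reflex_waveform(p, duration = 4.8, seed = 1)
  s <- rec$time - p$impact_time
  expected <- ifelse(s >= 0,
                     p$A * exp(-s / p$tau) * sin(2 * pi * p$f * s), 0)
  expect_equal(rec$angle, expected, tolerance = 1e-9)
})

test_that("velocity channel tracks the scaled numerical derivative", {
  p <- oracle_params()
  rec <- damped_reflex_waveform(p, duration = 4.8, seed = 1)
  fs <- rec$sample_rate
  idx <- which(rec$time > p$impact_time + 0.01)  # avoid onset kink
  idx <- idx[idx < length(rec$angle)]
  num_deriv <- (rec$angle[idx + 1] - rec$angle[idx - 1]) * fs / 2
  expect_lt(max(abs(p$gain_v * num_deriv - rec$velocity[idx])),
            0.01 * max(abs(rec$velocity)))
})

test_that("first positive peak lands at atan(w*tau)/w after impact", {
  p <- oracle_params(A = 50, f = 1.25, tau = 0.8)
  rec <- damped_reflex_waveform(p, duration = 4.8, seed = 1)
  w <- 2 * pi * p$f
  t_peak <- atan(w * p$tau) / w
  # independent numeric argmax over a dense grid
  dense <- seq(0, 1, by = 1e-5)
  t_dense <- dense[which.max(p$A * exp(-dense / p$tau) * sin(w * dense))]
  expect_lt(abs(t_peak - t_dense), 1e-5)
  expect_lt(abs(rec$time[which.max(rec$angle)] - p$impact_time - t_peak),
            1 / rec$sample_rate + 1e-9)
})

test_that("the impact channel is a 2 ms rectangular pulse at t0", {
  p <- generator_params(impact_time = 0.25, impact_amplitude = 5,
                        sigma_angle = 0, sigma_velocity = 0)
  rec <- damped_reflex_waveform(p, duration = 1, seed = 1)
  i0 <- which(rec$impact > 0)[1]
  expect_equal(rec$time[i0], 0.25, tolerance = 1e-9)
  on <- which(rec$impact == 5)
  expect_length(on, round(0.002 * rec$sample_rate))
  expect_identical(on, seq.int(i0, i0 + length(on) - 1L))
})

test_that("seeding is exact: same seed identical, different seeds differ", {
  p <- generator_params(sigma_angle = 1, sigma_velocity = 1)
  a <- damped_reflex_waveform(p, duration = 1, seed = 11)
  b <- damped_reflex_waveform(p, duration = 1, seed = 11)
  c <- damped_reflex_waveform(p, duration = 1, seed = 12)
  expect_identical(a$angle, b$angle)
  expect_identical(a$velocity, b$velocity)
  expect_false(identical(a$angle, c$angle))
})

test_that("under-sampled oscillation frequency raises an aliasing error", {
  expect_error(
    damped_reflex_waveform(generator_params(f = 300), sample_rate = 500),
    class = "reflexquant_aliasing_error")
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(generator_params(tau = 0), class = "reflexquant_usage_error")
  expect_error(generator_params(A = -1), class = "reflexquant_usage_error")
  expect_error(generator_params(sigma_angle = NA),
               class = "reflexquant_usage_error")
})

test_that("simulate_dataset honours counts, labels and determinism", {
  cheap <- lapply(ninds_levels(), function(g) oracle_params(A = 10))
  names(cheap) <- ninds_levels()

  expect_length(simulate_dataset(c("2+" = 0), seed = 1,
                                 params_by_grade = cheap, duration = 1), 0)

  counts <- c("0+" = 2, "1+" = 1, "2+" = 3, "3+" = 1)
  recs <- simulate_dataset(counts, seed = 5, params_by_grade = cheap,
                           duration = 1)
  expect_length(recs, 7)
  expect_identical(table(vapply(recs, function(r) r$label, character(1))),
                   table(factor(rep(names(counts), counts),
                                levels = names(counts))))
  expect_false(anyDuplicated(vapply(recs, function(r) r$subject_id,
                                    character(1))) > 0)

  again <- simulate_dataset(counts, seed = 5, params_by_grade = cheap,
                            duration = 1)
  expect_identical(lapply(recs, `[[`, "angle"), lapply(again, `[[`, "angle"))

  # per-recording streams are counter-derived: content does not depend on
  # which other grades are generated
  only2 <- simulate_dataset(c("2+" = 3), seed = 5, params_by_grade = cheap,
                            duration = 1)
  expect_identical(only2[[1]]$angle,
                   recs[[which(vapply(recs, `[[`, "", "label") == "2+")[1]]]$angle)
})

test_that("default dataset composition is 8/20/48/30", {
  cheap <- lapply(ninds_levels(), function(g) oracle_params(A = 5))
  names(cheap) <- ninds_levels()
  recs <- simulate_dataset(seed = 1, params_by_grade = cheap, duration = 1)
  expect_length(recs, 106)
  labs <- vapply(recs, `[[`, "", "label")
  expect_identical(as.integer(table(factor(labs, ninds_levels()))),
                   c(8L, 20L, 48L, 30L))
})

test_that("missing calibration for a requested grade raises", {
  cheap <- list("2+" = oracle_params())
  expect_error(simulate_dataset(c("2+" = 1, "3+" = 1), seed = 1,
                                params_by_grade = cheap, duration = 1),
               class = "reflexquant_calibration_error")
})
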