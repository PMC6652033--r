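# Synthetic reflex-recording generator.
#
# The post-impact knee angle is modelled as a single-mode exponentially damped
# sinusoid (the oscillatory swing of the leg) plus a slow aperiodic
# return-to-baseline component (the leg settling back to rest), plus additive
# Gaussian instrument noise:
#
#   angle(t) = A e^{-s/tau} sin(2 pi f s)
#            + B (e^{-s/tau_slow} - e^{-s/tau_rise})          s = t - t0 >= 0
#
# The velocity channel is an independently scaled sensor reading:
# gain_v * d(angle_deterministic)/dt plus its own noise. The impact channel is
# a rectangular 2 ms pulse at t0 (the tapping-sensor output).

#' Generator parameters for one synthetic reflex recording
#'
#' @param A Initial oscillation amplitude in degrees (>= 0).
#' @param f Oscillation frequency in Hz (> 0).
#' @param tau Oscillation envelope decay constant in seconds (> 0).
#' @param gain_v Dimensionless velocity-channel gain (> 0). The velocity
#'   channel is modelled as a scaled sensor reading, not the literal derivative
#'   of the angle trace: the published peak angular velocities are far below
#'   the analytic derivative of the published angular swings, consistent with
#'   an uncalibrated gyroscope scale.
#' @param sigma_angle SD of additive white noise on the angle channel, degrees.
#' @param sigma_velocity SD of additive white noise on the velocity channel,
#'   degrees/s.
#' @param impact_time Impact (pulse onset) time in seconds from record start.
#' @param impact_amplitude Impact pulse amplitude in volts (default 5).
#' @param baseline_amp Amplitude B (degrees) of the slow return-to-baseline
#'   component; 0 disables it, reducing the model to a pure damped sinusoid.
#' @param tau_slow Decay constant (s) of the baseline component.
#' @param tau_rise Rise constant (s) of the baseline component.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(A = 50, f = 1.25, tau = 0.8, gain_v = 0.08,
                             sigma_angle = 0.5, sigma_velocity = 0.5,
                             impact_time = 0.5, impact_amplitude = 5,
                             baseline_amp = 0, tau_slow = 3, tau_rise = 0.12) {
  p <- list(A = A, f = f, tau = tau, gain_v = gain_v,
            sigma_angle = sigma_angle, sigma_velocity = sigma_velocity,
            impact_time = impact_time, impact_amplitude = impact_amplitude,
            baseline_amp = baseline_amp, tau_slow = tau_slow,
            tau_rise = tau_rise)
  nums <- unlist(p)
  if (!all(is.finite(nums))) usage_error("all generator parameters must be finite")
  if (A < 0 || f <= 0 || tau <= 0 || gain_v <= 0 ||
      sigma_angle < 0 || sigma_velocity < 0 || impact_time < 0 ||
      baseline_amp < 0 || tau_slow <= 0 || tau_rise <= 0) {
    usage_error("generator parameter out of range (see ?generator_params)")
  }
  structure(p, class = "generator_params")
}

# Deterministic (noise-free) angle and velocity parts on a relative time grid
# s >= 0; used both by the generator and by the calibrator's energy algebra.
waveform_deterministic <- function(params, s) {
  w <- 2 * pi * params$f
  osc <- params$A * exp(-s / params$tau) * sin(w * s)
  drift <- params$baseline_amp *
    (exp(-s / params$tau_slow) - exp(-s / params$tau_rise))
  dosc <- params$A * exp(-s / params$tau) *
    (w * cos(w * s) - sin(w * s) / params$tau)
  ddrift <- params$baseline_amp *
    (-exp(-s / params$tau_slow) / params$tau_slow +
       exp(-s / params$tau_rise) / params$tau_rise)
  list(angle = osc + drift, velocity = params$gain_v * (dosc + ddrift))
}

#' Simulate one reflex recording from the damped-oscillation model
#'
#' With the same seed the output is bit-identical; with `sigma_angle = 0`,
#' `sigma_velocity = 0` and `baseline_amp = 0` the angle channel equals the
#' closed-form damped sinusoid exactly.
#'
#' @param params A [generator_params()] object.
#' @param duration Record length in seconds (default 4.8; must leave at least
#'   4 s after `impact_time` for the downstream analysis window).
#' @param sample_rate Sampling rate in Hz (default 5000).
#' @param seed Integer seed for the noise draws; `NULL` uses the current RNG
#'   stream.
#' @param subject_id,label Metadata stored in the recording.
#' @return A [reflex_recording()].
#' @export
damped_reflex_waveform <- function(params, duration = 4.8, sample_rate = 5000,
                                   seed = NULL, subject_id = "synthetic",
                                   label = NULL) {
  if (!inherits(params, "generator_params")) {
    usage_error("`params` must be a generator_params object")
  }
  if (sample_rate <= 2 * params$f) {
    aliasing_error(sprintf(
      "sample_rate (%g Hz) must exceed twice the oscillation frequency (%g Hz)",
      sample_rate, params$f))
  }
  n <- round(duration * sample_rate)
  if (n < 1L) usage_error("duration too short")
  tt <- (seq_len(n) - 1) / sample_rate
  pos <- tt >= params$impact_time
  if (!any(pos)) usage_error("impact_time lies beyond the record duration")
  s <- tt[pos] - params$impact_time

  det <- waveform_deterministic(params, s)
  angle <- numeric(n); angle[pos] <- det$angle
  velocity <- numeric(n); velocity[pos] <- det$velocity

  impact <- numeric(n)
  i0 <- which(pos)[1L]
  pulse_len <- max(1L, round(0.002 * sample_rate))
  impact[i0:min(n, i0 + pulse_len - 1L)] <- params$impact_amplitude

  with_seed(seed, {
    if (params$sigma_angle > 0) {
      angle <- angle + stats::rnorm(n, 0, params$sigma_angle)
    }
    if (params$sigma_velocity > 0) {
      velocity <- velocity + stats::rnorm(n, 0, params$sigma_velocity)
    }
  })

  reflex_recording(impact = impact, angle = angle, velocity = velocity,
                   sample_rate = sample_rate, subject_id = subject_id,
                   label = label, time = tt)
}

#' Published per-grade feature statistics used as calibration targets
#'
#' Returns, for each NINDS grade, the group mean and standard deviation of the
#' six features (peak-to-peak excursion `delta_a` in degrees, first-to-third
#' peak ratio `ratio_13`, max-to-min interval `delta_t1_ms` in milliseconds,
#' first-to-third peak interval `delta_t2_s` in seconds, 97% energy settling
#' time `ts_s` in seconds, and peak angular velocity `vmax` in degrees/s).
#' The first-to-third peak interval is reported in seconds: values of 1.6-1.8
#' spanning two ~1.2 Hz oscillation periods are only physically consistent
#' with seconds given max-to-min intervals of 350-440 ms.
#'
#' @return Named list (one element per grade) of data frames with columns
#'   `feature`, `mean`, `sd`.
#' @export
default_group_targets <- function() {
  mk <- function(m, s) data.frame(feature = FEATURE_COLS, mean = m, sd = s,
                                  stringsAsFactors = FALSE)
  list(
    "0+" = mk(c(3.45, 0.82, 108, 1.78, 0.89, 2.73),
              c(1.93, 0.30, 71, 0.244, 0.318, 1.96)),
    "1+" = mk(c(24.52, 0.144, 354, 1.57, 1.97, 10.34),
              c(8.4, 0.12, 68, 0.164, 0.766, 5.06)),
    "2+" = mk(c(59.57, 0.156, 414, 1.73, 2.41, 26.97),
              c(12.41, 0.16, 64, 0.173, 0.785, 9.66)),
    "3+" = mk(c(93.83, 0.135, 440, 1.79, 2.53, 38.71),
              c(18.39, 0.16, 52, 0.222, 0.773, 9.53)))
}

target_value <- function(targets, feature, what = "mean") {
  targets[[what]][match(feature, targets$feature)]
}

# Multiplicative truncated-Gaussian jitter factors reproducing between-subject
# spread. z is truncated at +/- 2.5 SD and factors floored at 0.1.
jitter_factor <- function(n, rel_sd, floor = 0.1) {
  if (rel_sd <= 0) return(rep(1, n))
  z <- stats::qnorm(stats::runif(n, stats::pnorm(-2.5), stats::pnorm(2.5)))
  pmax(1 + rel_sd * z, floor)
}

# Per-grade jitter scales derived once from the published relative SDs:
# amplitude jitter from delta_a, velocity-gain jitter from vmax (in excess of
# the amplitude contribution), decay jitter from the peak-ratio spread scaled
# by the log-sensitivity d log(ratio)/d log(tau) = delta_t2/tau, and a fixed
# spread on the baseline component driving the settling-time spread.
jitter_from_targets <- function(targets, tau) {
  rel <- function(feat) {
    m <- target_value(targets, feat, "mean")
    s <- target_value(targets, feat, "sd")
    if (abs(m) < 1e-12) 0 else s / abs(m)
  }
  jA <- min(rel("delta_a"), 0.45)
  jg <- min(sqrt(max(rel("vmax")^2 - jA^2, 0.02^2)), 0.45)
  dt2 <- target_value(targets, "delta_t2_s", "mean")
  sens <- max(dt2 / tau, 0.5)
  jtau <- min(max(rel("ratio_13") / sens, 0.05), 0.30)
  list(A = jA, gain_v = jg, tau = jtau, baseline = 0.30)
}

# Deterministic per-recording seed independent of generation order.
recording_seed <- function(master_seed, grade_index, k) {
  as.integer((as.numeric(master_seed) %% 1e6) * 2000 +
               grade_index * 400 + k) %% 2147483647L
}

# Draw one jittered parameter set inside the recording's own RNG stream.
jittered_params <- function(params, jitter) {
  fA <- jitter_factor(1, jitter$A)
  # decay and baseline draws are floored harder: a decay constant below half
  # its nominal value leaves no identifiable peak train, which real graded
  # responses retain
  ftau <- jitter_factor(1, jitter$tau, floor = 0.5)
  fg <- jitter_factor(1, jitter$gain_v)
  fB <- jitter_factor(1, jitter$baseline, floor = 0.25)
  generator_params(
    A = params$A * fA, f = params$f, tau = params$tau * ftau,
    gain_v = params$gain_v * fg,
    sigma_angle = params$sigma_angle, sigma_velocity = params$sigma_velocity,
    impact_time = params$impact_time,
    impact_amplitude = params$impact_amplitude,
    baseline_amp = params$baseline_amp * fB,
    tau_slow = params$tau_slow, tau_rise = params$tau_rise)
}

#' Simulate a labelled dataset of reflex recordings
#'
#' Generates `counts[g]` recordings per NINDS grade from per-grade calibrated
#' generator parameters, with multiplicative truncated-Gaussian jitter on the
#' amplitude, decay constant, velocity gain and baseline amplitude so that the
#' between-subject feature spread approximates the published group SDs. Each
#' recording draws from its own counter-derived RNG stream, so the dataset
#' content is reproducible under the master seed and independent of generation
#' order. The default counts reproduce the published cohort composition
#' (8/20/48/30 for grades 0+ to 3+, 106 recordings).
#'
#' @param counts Named integer vector of recordings per grade.
#' @param seed Master integer seed.
#' @param params_by_grade Optional named list of [generator_params()] per
#'   grade; when `NULL` the grades in `counts` are calibrated against
#'   [default_group_targets()] (cached per seed/config within the session).
#' @param config A [pipeline_config()]; fixes the preprocessing and
#'   peak-detection settings the calibration inverts through.
#' @param duration,sample_rate Record geometry passed to the generator.
#' @return List of [reflex_recording()] objects with labels attached.
#' @export
simulate_dataset <- function(counts = c("0+" = 8, "1+" = 20, "2+" = 48, "3+" = 30),
                             seed = 1, params_by_grade = NULL,
                             config = pipeline_config(),
                             duration = 4.8, sample_rate = 5000) {
  grades <- names(counts)
  if (is.null(grades) || !all(grades %in% ninds_levels())) {
    usage_error("`counts` must be a named vector over NINDS grades 0+..3+")
  }
  if (any(counts < 0)) usage_error("counts must be non-negative")
  active <- grades[counts > 0]
  if (is.null(params_by_grade)) {
    params_by_grade <- calibrate_all_groups(
      grades = active, config = config, seed = seed,
      duration = duration, sample_rate = sample_rate)
  }
  missing_cal <- setdiff(active, names(params_by_grade))
  if (length(missing_cal) > 0L) {
    calibration_error(sprintf("missing calibration for grade(s): %s",
                              paste(missing_cal, collapse = ", ")))
  }

  targets <- default_group_targets()
  recs <- list()
  for (g in active) {
    gi <- match(g, ninds_levels())
    base <- params_by_grade[[g]]
    jit <- jitter_from_targets(targets[[g]], base$tau)
    for (k in seq_len(counts[[g]])) {
      rseed <- recording_seed(seed, gi, k)
      rec <- with_seed(rseed, {
        pk <- jittered_params(base, jit)
        damped_reflex_waveform(pk, duration = duration,
                               sample_rate = sample_rate, seed = NULL,
                               subject_id = sprintf("g%s_%03d",
                                                    sub("\\+", "p", g), k),
                               label = g)
      })
      recs[[length(recs) + 1L]] <- rec
    }
  }
  recs
}
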