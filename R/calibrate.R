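# Calibration of the generator against published per-grade feature targets.
#
# The inversion is mostly closed-form. For a damped sinusoid
# A e^{-s/tau} sin(2 pi f s):
#   * the max-to-min interval is half a period  -> f from delta_t1,
#   * the first-to-third-peak interval is two periods -> f from delta_t2,
#   * the peak ratio is exp(-delta_t2/tau)      -> tau,
#   * the peak/trough amplitudes follow from (f, tau) -> A from delta_a,
#   * the peak velocity is ~ gain_v * A * 2 pi f -> gain_v from vmax,
#   * the 97% energy crossing of the noiseless oscillation is ~1.75 tau; the
#     published settling times exceed that, and the gap is carried by the slow
#     return-to-baseline component, whose amplitude B is solved from the
#     cumulative-energy equation.
# A short fixed-point refinement then pushes the *pipeline-extracted* feature
# means (which include filtering, noise and between-subject jitter effects)
# onto the targets with damped multiplicative corrections.

# closed-form initialisers -------------------------------------------------

calib_init_f <- function(delta_t2_s) 2 / delta_t2_s

calib_init_tau <- function(delta_t2_s, ratio_13) {
  r <- min(max(ratio_13, 1e-3), 0.95)
  delta_t2_s / log(1 / r)
}

# Amplitude of the first peak and first trough of e^{-s/tau} sin(w s),
# relative to A.
osc_peak_factors <- function(f, tau) {
  w <- 2 * pi * f
  tp <- atan(w * tau) / w
  peak <- exp(-tp / tau) * sin(w * tp)
  tr <- tp + pi / w
  trough <- exp(-tr / tau) * abs(sin(w * tr))
  list(peak = peak, trough = trough, span = peak + trough)
}

# RMS gain of the zero-phase low-pass for white noise, computed from the
# two-pass impulse response; deterministic, cached per design.
.noise_gain_cache <- new.env(parent = emptyenv())
filter_noise_gain <- function(sample_rate, filter_cfg) {
  key <- paste(sample_rate, filter_cfg$order, filter_cfg$cutoff,
               filter_cfg$ripple_db, sep = "|")
  if (!is.null(.noise_gain_cache[[key]])) return(.noise_gain_cache[[key]])
  n <- 8192L
  x <- numeric(n); x[n %/% 2L] <- 1
  h <- lowpass_filter(x, sample_rate, order = filter_cfg$order,
                      cutoff = filter_cfg$cutoff,
                      ripple_db = filter_cfg$ripple_db)
  g <- sqrt(sum(h^2))
  .noise_gain_cache[[key]] <- g
  g
}

# Predicted settling time of the deterministic waveform plus a white noise
# floor of post-filter SD sigma_post, on the 4-s analysis grid.
predict_settling <- function(params, sigma_post, trim_duration, sample_rate) {
  n <- round(trim_duration * sample_rate)
  s <- (seq_len(n) - 1) / sample_rate
  det <- waveform_deterministic(params, s)$angle
  e <- cumsum(det^2) + sigma_post^2 * seq_len(n)
  idx <- which(e >= 0.97 * e[n])[1L]
  (idx - 1) / sample_rate
}

# Solve for the baseline amplitude B that puts the predicted settling time at
# ts_goal (monotone in B); returns 0 when the waveform already settles late
# enough.
solve_baseline <- function(params, sigma_post, ts_goal, trim_duration,
                           sample_rate) {
  pred <- function(B) {
    p <- params; p$baseline_amp <- B
    predict_settling(p, sigma_post, trim_duration, sample_rate)
  }
  if (pred(0) >= ts_goal) return(0)
  b_max <- max(20 * params$A, 1)
  if (pred(b_max) <= ts_goal) return(b_max)
  stats::uniroot(function(B) pred(B) - ts_goal, c(0, b_max), tol = 1e-4)$root
}

# Simulate n jittered recordings from `params` and return the mean extracted
# feature vector (full preprocess + extraction pipeline).
sim_feature_means <- function(params, jitter, n, seed_base, grade_index,
                              config, duration, sample_rate) {
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    rseed <- recording_seed(seed_base, grade_index, k)
    rows[[k]] <- with_seed(rseed, {
      pk <- jittered_params(params, jitter)
      rec <- damped_reflex_waveform(pk, duration = duration,
                                    sample_rate = sample_rate, seed = NULL)
      extract_features(preprocess_recording(rec, config), config)
    })
  }
  colMeans(do.call(rbind, rows)[, FEATURE_COLS])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Calibrate generator parameters for one NINDS grade
#'
#' Inverts the published feature targets through the full
#' preprocess-and-extract pipeline: closed-form initialisation (see the file
#' header) followed by a damped fixed-point refinement of `(A, f, tau,
#' gain_v, baseline_amp)` against the feature means of `n_sim` seeded,
#' jittered simulations per round.
#'
#' Convergence is assessed on the envelope features the waveform family
#' always controls (`delta_a`, `delta_t1_ms`, `ts_s`, `vmax`): each must land
#' within 10% relative (0.25 absolute for targets below 2) of its target.
#' Residuals for the peak-train features (`ratio_13`, `delta_t2_s`) are
#' reported in the `diagnostics` attribute; they converge equally for
#' internally consistent target sets, but an absent-reflex (0+) target row
#' cannot satisfy them jointly with its settling time under any decaying
#' waveform (see the methods vignette) and is matched best-effort.
#'
#' @param targets Data frame with columns `feature`, `mean`, `sd` as returned
#'   by [default_group_targets()] for one grade.
#' @param config A [pipeline_config()].
#' @param n_sim Simulations per refinement round.
#' @param rounds Refinement rounds (the last round only measures).
#' @param seed Integer seed for the refinement simulations.
#' @param duration,sample_rate Record geometry.
#' @param grade_index Integer 1-4 used to derive per-recording seeds.
#' @param strict Raise a calibration error when an envelope feature misses
#'   its target by more than twice the tolerance (clear divergence); smaller
#'   misses, which are within the Monte-Carlo noise of the measurement
#'   batch for the high-variance grades, always warn.
#' @return A [generator_params()] object with a `diagnostics` attribute
#'   (measured means, targets, residuals).
#' @export
calibrate_group <- function(targets, config = pipeline_config(), n_sim = 64,
                            rounds = 4, seed = 1, duration = 4.8,
                            sample_rate = 5000, grade_index = 1L,
                            strict = TRUE) {
  tv <- function(feat) target_value(targets, feat)
  if (!all(is.finite(targets$mean)) || any(targets$sd < 0)) {
    usage_error("targets must have finite means and non-negative sds")
  }
  dt1 <- tv("delta_t1_ms") / 1000
  dt2 <- tv("delta_t2_s")
  f1 <- 1 / (2 * dt1)           # f implied by the max-to-min interval
  f2 <- calib_init_f(dt2)       # f implied by the first-to-third interval
  coherent <- abs(log(f1 / f2)) <= log(1.5)
  f <- if (coherent) f2 else f1 # incoherent target rows: trust delta_t1

  ts_t <- tv("ts_s")
  tau <- min(calib_init_tau(2 / f, tv("ratio_13")),
             0.95 * ts_t / 1.753)
  tau <- max(tau, 0.05)

  fac <- osc_peak_factors(f, tau)
  A <- tv("delta_a") / fac$span
  gain_v <- tv("vmax") / (A * 2 * pi * f)

  kappa <- filter_noise_gain(sample_rate, config$filter)
  sigma_post <- max(0.02, 0.004 * tv("delta_a"))
  sigma_angle <- sigma_post / kappa
  sigma_velocity <- max(0.02, 0.008 * tv("vmax")) / kappa

  build <- function(A, f, tau, gain_v, B, tau_slow = 3) generator_params(
    A = A, f = f, tau = tau, gain_v = gain_v,
    sigma_angle = sigma_angle, sigma_velocity = sigma_velocity,
    baseline_amp = B, tau_slow = tau_slow)
  B0 <- solve_baseline(build(A, f, tau, gain_v, 0), sigma_post, ts_t,
                       config$trim_duration, sample_rate)

  # --- deterministic refinement -------------------------------------------
  # The noiseless waveform pushed through the actual preprocess+extract
  # pipeline is a deterministic forward model; Nelder-Mead in log-parameter
  # space minimises the tolerance-scaled squared residuals. Tolerances mirror
  # the recovery contract (10% relative, 0.25 absolute below 2; the peak
  # ratio gets a 0.05 absolute floor since its targets are small). For
  # incoherent target rows the peak-train features are unweighted: no
  # decaying waveform can reconcile them with the envelope features. A trust
  # region keeps tau within [1/1.8, 1.8] of its closed-form value for
  # coherent rows, so the optimiser cannot trade the oscillatory peak train
  # for a drift-dominated corner that is fragile under between-subject
  # jitter.
  tgt <- vapply(FEATURE_COLS, tv, numeric(1))
  tol <- pmax(0.1 * abs(tgt), ifelse(abs(tgt) < 2, 0.25, 0))
  tol[["ratio_13"]] <- max(0.1 * tgt[["ratio_13"]], 0.10)
  wts <- stats::setNames(rep(1, 6), FEATURE_COLS)
  wts[["ts_s"]] <- 1.5
  if (!coherent) wts[c("ratio_13", "delta_t2_s")] <- 0
  # out-of-band barrier: keeping every feature inside its tolerance band
  # takes precedence over centring any single feature within it; the envelope
  # features carry the stronger barrier
  barrier <- stats::setNames(rep(4, 6), FEATURE_COLS)
  barrier[c("delta_a", "delta_t1_ms", "ts_s", "vmax")] <- 10
  barrier[wts == 0] <- 0
  tau_cf <- tau

  det_features <- function(A, f, tau, gain_v, B, tau_slow = 3) {
    p <- build(A, f, tau, gain_v, B, tau_slow)
    p$sigma_angle <- 0
    p$sigma_velocity <- 0
    rec <- damped_reflex_waveform(p, duration = duration,
                                  sample_rate = sample_rate, seed = NULL)
    extract_features(preprocess_recording(rec, config), config)
  }
  det_fit <- function(start, goal, maxit) {
    obj <- function(par) {
      v <- exp(par)
      fv <- tryCatch(det_features(v[1], v[2], v[3], v[4], v[5] - 1e-6, v[6]),
                     error = function(e) NULL)
      if (is.null(fv)) return(1e6)
      res <- (unlist(fv[FEATURE_COLS]) - goal) / tol
      band <- (unlist(fv[FEATURE_COLS]) - tgt) / tol
      pen <- if (coherent) {
        100 * max(0, abs(log(v[3] / tau_cf)) - log(1.8))^2
      } else 0
      # keep the baseline component slow relative to the oscillation but
      # inside the analysis window
      pen <- pen + 100 * max(0, abs(log(v[6] / 3.5)) - log(2.4))^2
      # and subordinate to the oscillation: drift-dominated waveforms lose
      # their peak train under between-subject jitter
      pen <- pen + 50 * max(0, v[5] / v[1] - 0.2)^2
      sum(wts * res^2 + barrier * pmax(0, abs(band) - 1)^2) + pen
    }
    fit <- stats::optim(log(start), obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-8))
    # restart from the optimum: Nelder-Mead simplices collapse on ridges
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit %/% 2, reltol = 1e-8))
    exp(fit$par)
  }

  v <- det_fit(c(A, f, tau, gain_v, B0 + 1e-6, 3), tgt, maxit = 600)

  # --- stochastic bias correction -----------------------------------------
  # Noise, between-subject jitter and occasional degenerate traces shift the
  # pipeline means off the deterministic optimum. Each round measures that
  # offset on n_sim seeded simulations and re-fits the deterministic model
  # against offset-corrected targets (a stable correction: the deterministic
  # fit is well-conditioned, and the offsets are small and nearly constant).
  seed_base <- (seed + 104729) %% 2147483647
  meas <- NULL
  offsets <- NULL
  for (r in seq_len(rounds)) {
    params <- build(v[1], v[2], max(v[3], 0.05), v[4], max(v[5] - 1e-6, 0),
                    v[6])
    jitter <- jitter_from_targets(targets, params$tau)
    meas <- sim_feature_means(params, jitter, n_sim, seed_base + 13 * r,
                              grade_index, config, duration, sample_rate)
    if (r == rounds) break
    pred <- unlist(det_features(params$A, params$f, params$tau,
                                params$gain_v, params$baseline_amp,
                                params$tau_slow)[FEATURE_COLS])
    # offsets are averaged over rounds: each round's estimate carries the
    # Monte-Carlo noise of its n_sim batch, and chasing a single batch
    # overfits the correction
    offsets <- rbind(offsets, clamp(meas - pred, -2 * tol, 2 * tol))
    goal <- tgt - colMeans(offsets)
    goal[["ratio_13"]] <- max(goal[["ratio_13"]], 0.02)
    goal[["ts_s"]] <- clamp(goal[["ts_s"]], 0.1, 3.8)
    goal[["delta_a"]] <- max(goal[["delta_a"]], 0.1 * tgt[["delta_a"]])
    goal[["vmax"]] <- max(goal[["vmax"]], 0.1 * tgt[["vmax"]])
    v <- det_fit(v, goal, maxit = 300)
  }
  params <- build(v[1], v[2], max(v[3], 0.05), v[4], max(v[5] - 1e-6, 0),
                  v[6])
  jitter <- jitter_from_targets(targets, params$tau)

  envelope <- c("delta_a", "delta_t1_ms", "ts_s", "vmax")
  resid <- vapply(FEATURE_COLS, function(feat) {
    m <- meas[[feat]]; t <- tv(feat)
    if (abs(t) < 2) min(abs(m - t) / max(abs(t), 1e-9), abs(m - t) / 0.25 * 0.1)
    else abs(m - t) / abs(t)
  }, numeric(1))
  worst <- names(which.max(resid[envelope]))
  if (max(resid[envelope]) > 0.1) {
    msg <- sprintf(
      "calibration did not converge: worst envelope residual %s = %.1f%% (measured %.4g, target %.4g)",
      worst, 100 * max(resid[envelope]), meas[[worst]], tv(worst))
    # below 20% the discrepancy is within the Monte-Carlo noise of a
    # finite measurement batch for the high-variance grades; only a clear
    # divergence is fatal
    if (strict && max(resid[envelope]) > 0.2) calibration_error(msg)
    warning(msg)
  }
  attr(params, "diagnostics") <- list(measured = meas,
                                      targets = stats::setNames(targets$mean,
                                                                targets$feature),
                                      residual = resid, jitter = jitter)
  params
}

.calib_cache <- new.env(parent = emptyenv())

#' Calibrate all requested NINDS grades (with session caching)
#'
#' @param grades Character vector of grades to calibrate.
#' @param targets Per-grade target list, default [default_group_targets()].
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @param duration,sample_rate Record geometry.
#' @param ... Passed to [calibrate_group()].
#' @return Named list of [generator_params()].
#' @export
calibrate_all_groups <- function(grades = ninds_levels(),
                                 targets = default_group_targets(),
                                 config = pipeline_config(), seed = 1,
                                 duration = 4.8, sample_rate = 5000, ...) {
  out <- list()
  for (g in grades) {
    gi <- match(g, ninds_levels())
    key <- paste(g, seed, config_key(config, duration, sample_rate), sep = "#")
    if (is.null(.calib_cache[[key]])) {
      .calib_cache[[key]] <- calibrate_group(
        targets[[g]], config = config, seed = seed, duration = duration,
        sample_rate = sample_rate, grade_index = gi, ...)
    }
    out[[g]] <- .calib_cache[[key]]
  }
  out
}

#' Feature-recovery study: calibrated simulation vs published group means
#'
#' For each requested grade, calibrates the generator, simulates `n` fresh
#' jittered recordings (seeded independently of the calibration runs), pushes
#' them through the full preprocessing and feature-extraction pipeline, and
#' tabulates the extracted feature means next to the published targets.
#'
#' @param grades Grades to study.
#' @param n Recordings per grade.
#' @param seed Master seed.
#' @param config A [pipeline_config()].
#' @param duration,sample_rate Record geometry.
#' @return A data frame with columns `grade`, `feature`, `target_mean`,
#'   `simulated_mean`, `n`.
#' @export
feature_recovery_study <- function(grades = ninds_levels(), n = 100, seed = 1,
                                   config = pipeline_config(),
                                   duration = 4.8, sample_rate = 5000) {
  targets <- default_group_targets()
  params <- calibrate_all_groups(grades, targets, config, seed = seed,
                                 duration = duration,
                                 sample_rate = sample_rate)
  out <- list()
  for (g in grades) {
    counts <- stats::setNames(n, g)
    recs <- simulate_dataset(counts, seed = seed + 31 * match(g, ninds_levels()),
                             params_by_grade = params[g], config = config,
                             duration = duration, sample_rate = sample_rate)
    tbl <- extract_dataset_features(recs, config)
    means <- colMeans(as.matrix(tbl[, FEATURE_COLS]))
    out[[g]] <- data.frame(grade = g, feature = FEATURE_COLS,
                           target_mean = targets[[g]]$mean,
                           simulated_mean = as.numeric(means[FEATURE_COLS]),
                           n = n, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
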