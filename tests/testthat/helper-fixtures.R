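# Shared fixture builders. Everything is generated in code; no stored data.

# A small deterministic recording with distinctive channel contents.
tiny_recording <- function(n = 50, sample_rate = 5000, label = "2+",
                           subject_id = "fix_001") {
  reflex_recording(
    impact = c(rep(0, 5), rep(5, 3), rep(0, n - 8)),
    angle = sin(seq_len(n) / 3) * 12.5 + 0.001 * seq_len(n),
    velocity = cos(seq_len(n) / 4) * 30,
    sample_rate = sample_rate, subject_id = subject_id, label = label)
}

# Noise-free damped-sinusoid generator parameters used by the oracle tests.
oracle_params <- function(A = 50, f = 1.25, tau = 0.8, gain_v = 0.08) {
  generator_params(A = A, f = f, tau = tau, gain_v = gain_v,
                   sigma_angle = 0, sigma_velocity = 0, baseline_amp = 0)
}

# Wrap a bare angle/velocity pair as a trimmed recording (bypassing the
# preprocessing stage) for direct feature-extraction tests.
as_trimmed <- function(angle, velocity = NULL, sample_rate = 5000) {
  if (is.null(velocity)) velocity <- numeric(length(angle))
  structure(list(angle = angle, velocity = velocity,
                 sample_rate = sample_rate, t0_index = 1L,
                 subject_id = "trim_fix", label = NULL),
            class = "trimmed_recording")
}

# A small labelled feature table with separable groups (no pipeline runs).
toy_feature_table <- function(n_per_group = 4, seed = 7) {
  set.seed(seed)
  grades <- ninds_levels()
  centers <- list("0+" = c(3, 3), "1+" = c(25, 10), "2+" = c(60, 27),
                  "3+" = c(94, 39))
  rows <- do.call(rbind, lapply(grades, function(g) {
    data.frame(
      subject_id = sprintf("%s_%d", sub("\\+", "p", g), seq_len(n_per_group)),
      label = g,
      delta_a = centers[[g]][1] + rnorm(n_per_group, 0, 2),
      ratio_13 = runif(n_per_group, 0.1, 0.3),
      delta_t1_ms = 300 + rnorm(n_per_group, 0, 30),
      delta_t2_s = 1.6 + rnorm(n_per_group, 0, 0.1),
      ts_s = 2 + rnorm(n_per_group, 0, 0.2),
      vmax = centers[[g]][2] + rnorm(n_per_group, 0, 1.5),
      stringsAsFactors = FALSE)
  }))
  labeled_feature_table(rows$subject_id, rows$label,
                        rows[, c("delta_a", "ratio_13", "delta_t1_ms",
                                 "delta_t2_s", "ts_s", "vmax")])
}

# Closed-form two-pass magnitude of the digital Chebyshev type-I low-pass at
# frequency f_hz (bilinear-transform design, hence the tan() prewarp).
cheby1_two_pass_gain <- function(f_hz, cutoff, sample_rate, order = 3,
                                 ripple_db = 0.5) {
  x <- tan(pi * f_hz / sample_rate) / tan(pi * cutoff / sample_rate)
  tn <- if (abs(x) <= 1) cos(order * acos(x)) else cosh(order * acosh(abs(x)))
  eps2 <- 10^(ripple_db / 10) - 1
  1 / (1 + eps2 * tn^2)   # |H|^2 = squared single-pass magnitude
}

# Least-squares amplitude of a known-frequency sinusoid in the central
# portion of a series (edges dropped to avoid transient contamination).
fitted_amplitude <- function(y, f_hz, sample_rate, drop_s = 0.5) {
  n <- length(y)
  idx <- seq.int(round(drop_s * sample_rate) + 1,
                 n - round(drop_s * sample_rate))
  tt <- (idx - 1) / sample_rate
  X <- cbind(sin(2 * pi * f_hz * tt), cos(2 * pi * f_hz * tt))
  cf <- stats::lm.fit(X, y[idx])$coefficients
  sqrt(sum(cf^2))
}

# A minimal labelled table with chosen per-group delta_a values (vmax = v/2).
make_two_group_table <- function(values_by_group) {
  grades <- names(values_by_group)
  rows <- do.call(rbind, lapply(grades, function(g) {
    v <- values_by_group[[g]]
    data.frame(subject_id = sprintf("%s_%d", sub("\\+", "p", g), seq_along(v)),
               label = g, delta_a = v, ratio_13 = 0.2, delta_t1_ms = 400,
               delta_t2_s = 1.6, ts_s = 2, vmax = v / 2,
               stringsAsFactors = FALSE)
  }))
  labeled_feature_table(rows$subject_id, rows$label, rows[, 3:8])
}


# Exhaustive-permutation oracle, written independently of the package: mid
# ranks, tie-corrected H from the rank formula, all 1680 assignments for
# n = (3,3,3).
perm_kw_oracle <- function(groups) {
  vals <- unlist(groups)
  sizes <- lengths(groups)
  n <- length(vals)
  h_of <- function(assign) {
    r <- rank(vals)  # mid-ranks
    grp <- rep(seq_along(sizes), sizes)[order(assign)]
    # assignment: position i of vals belongs to group grp[i]
    rb <- tapply(r, grp, mean)
    h <- 12 / (n * (n + 1)) * sum(sizes * (rb - (n + 1) / 2)^2)
    ties <- table(vals)
    h / (1 - sum(ties^3 - ties) / (n^3 - n))
  }
  ids <- seq_len(n)
  h_obs <- h_of(ids)
  picks1 <- utils::combn(ids, sizes[1], simplify = FALSE)
  total <- 0L; ge <- 0L
  for (p1 in picks1) {
    rest1 <- setdiff(ids, p1)
    picks2 <- utils::combn(rest1, sizes[2], simplify = FALSE)
    for (p2 in picks2) {
      assign <- c(p1, p2, setdiff(rest1, p2))
      total <- total + 1L
      if (h_of(assign) >= h_obs - 1e-9) ge <- ge + 1L
    }
  }
  ge / total
}

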