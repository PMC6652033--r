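# Extraction of the six biomechanical features from a trimmed recording.

#' Find local maxima and minima with prominence and spacing rules
#'
#' Candidate extrema are strict local maxima/minima; candidates below the
#' prominence floor are dropped, then a minimum spacing is enforced greedily
#' by magnitude (when two candidates are closer than `min_distance`, the one
#' with larger absolute value is kept).
#'
#' @param series Numeric vector (length >= 3).
#' @param sample_rate Sampling rate in Hz.
#' @param min_distance Minimum spacing between same-kind peaks, seconds.
#' @param min_prominence Prominence floor; defaults to 2% of the series range.
#' @return A list of class `peak_list` with data frames `maxima` and `minima`
#'   (columns `index`, `time`, `value`), each ordered by time. Empty frames
#'   are allowed.
#' @export
find_peaks <- function(series, sample_rate, min_distance = 0.1,
                       min_prominence = NULL) {
  if (length(series) < 3L) usage_error("series must have at least 3 samples")
  if (is.null(min_prominence)) {
    min_prominence <- 0.02 * (max(series) - min(series))
  }
  structure(
    list(maxima = find_extrema(series, sample_rate, min_distance,
                               min_prominence, maxima = TRUE),
         minima = find_extrema(series, sample_rate, min_distance,
                               min_prominence, maxima = FALSE)),
    class = "peak_list")
}

# One-sided extrema finder; minima are found as maxima of the negated series.
# Spacing is enforced first (greedy by peak height in the list's direction:
# of two maxima closer than min_distance the higher is kept, of two minima
# the lower), then exact topographic prominence is computed for the few
# survivors. Height-directed spacing keeps genuine small late peaks from
# being displaced by noise wiggles sitting lower on an adjacent flank.
find_extrema <- function(series, sample_rate, min_distance, min_prominence,
                         maxima = TRUE) {
  x <- if (maxima) series else -series
  empty <- data.frame(index = integer(0), time = numeric(0),
                      value = numeric(0))
  d2 <- diff(sign(diff(x)))
  cand <- which(d2 < 0) + 1L
  if (length(cand) == 0L) return(empty)

  min_gap <- min_distance * sample_rate
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0L || all(abs(kept - i) >= min_gap)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)

  prom <- peak_prominence(x, kept)
  kept <- kept[prom >= min_prominence]
  if (length(kept) == 0L) return(empty)
  data.frame(index = kept, time = (kept - 1) / sample_rate,
             value = series[kept])
}

# Topographic prominence of candidate maxima of x: peak value minus the higher
# of the two key saddles (the lowest point on the path to higher ground on
# each side, or to the series edge).
peak_prominence <- function(x, cand) {
  n <- length(x)
  vapply(cand, function(i) {
    v <- x[i]
    left <- if (i == 1L) v else {
      higher <- which(x[seq_len(i - 1L)] > v)
      lo <- if (length(higher) == 0L) 1L else max(higher)
      min(x[lo:i])
    }
    right <- if (i == n) v else {
      seg <- x[seq.int(i + 1L, n)]
      higher <- which(seg > v)
      hi <- if (length(higher) == 0L) n else i + min(higher)
      min(x[i:hi])
    }
    v - max(left, right)
  }, numeric(1))
}

#' Settling time: the 97% cumulative-energy crossing
#'
#' Computes the cumulative energy E(t) = sum of squared samples up to t and
#' returns the earliest time at which E reaches `fraction` of the total energy
#' in the window. Time is measured from the window start; a single impulse at
#' the first sample therefore settles at 0 s and a constant-amplitude series
#' over 4 s settles at 0.97 x 4 = 3.88 s.
#'
#' @param series Numeric vector (not all zero).
#' @param sample_rate Sampling rate in Hz.
#' @param fraction Energy fraction defining settling (default 0.97).
#' @return Settling time in seconds.
#' @export
settling_time <- function(series, sample_rate, fraction = 0.97) {
  e <- cumsum(series^2)
  total <- e[length(e)]
  if (total <= 0) degenerate_signal_error("all-zero series has no settling time")
  idx <- which(e >= fraction * total)[1L]
  (idx - 1) / sample_rate
}

#' Extract the six biomechanical features from a trimmed recording
#'
#' From the filtered angle channel: `delta_a`, the difference between the
#' global maximum and minimum; `delta_t1_ms`, the interval between them in
#' milliseconds; `ratio_13` and `delta_t2_s` from the first (P1) and third
#' (P3) positive local maxima (the later peak over the first, so the ratio of
#' a decaying train is below 1, matching the published group values); and
#' `ts_s`, the 97% energy settling time. From the filtered velocity channel:
#' `vmax`, the signed maximum (configurable to absolute).
#'
#' When fewer than three positive maxima are detected, P1/P3 fall back to the
#' first three local maxima of `|angle|`; if even those are unavailable the
#' recording is degenerate: with `config$impute_degenerate` the ratio is
#' imputed as 1 and the peak interval as 0 (keeping absent-reflex rows usable
#' downstream), otherwise a feature error is raised.
#'
#' @param trimmed A `trimmed_recording` (see [preprocess_recording()]).
#' @param config A [pipeline_config()]; supplies the peak-detection settings
#'   and imputation policy.
#' @return A one-row data frame with the six feature columns plus a logical
#'   `degenerate` flag.
#' @export
extract_features <- function(trimmed, config = pipeline_config()) {
  angle <- trimmed$angle
  velocity <- trimmed$velocity
  fs <- trimmed$sample_rate

  ts_s <- settling_time(angle, fs)   # raises on all-zero input

  i_max <- which.max(angle)
  i_min <- which.min(angle)
  delta_a <- angle[i_max] - angle[i_min]
  delta_t1_ms <- abs(i_max - i_min) / fs * 1000

  pk <- config$peaks
  min_prom <- pk$min_prominence_frac * (max(angle) - min(angle))
  peaks <- find_peaks(angle, fs, min_distance = pk$min_distance,
                      min_prominence = min_prom)
  pos <- peaks$maxima[peaks$maxima$value > 0, , drop = FALSE]

  degenerate <- FALSE
  if (nrow(pos) >= 3L) {
    ratio_13 <- pos$value[3L] / pos$value[1L]
    delta_t2_s <- pos$time[3L] - pos$time[1L]
  } else {
    abs_pk <- find_peaks(abs(angle), fs, min_distance = pk$min_distance,
                         min_prominence = min_prom)$maxima
    if (nrow(abs_pk) >= 3L) {
      ratio_13 <- abs_pk$value[3L] / abs_pk$value[1L]
      delta_t2_s <- abs_pk$time[3L] - abs_pk$time[1L]
    } else if (isTRUE(config$impute_degenerate)) {
      ratio_13 <- 1
      delta_t2_s <- 0
      degenerate <- TRUE
    } else {
      feature_error(
        "fewer than 3 detectable peaks: ratio_13 and delta_t2_s are undefined")
    }
  }

  vmax <- if (isTRUE(config$vmax_absolute)) max(abs(velocity)) else max(velocity)

  out <- data.frame(delta_a = delta_a, ratio_13 = ratio_13,
                    delta_t1_ms = delta_t1_ms, delta_t2_s = delta_t2_s,
                    ts_s = ts_s, vmax = vmax, degenerate = degenerate)
  validate_feature_vector(out)
  out
}

validate_feature_vector <- function(fv) {
  if (fv$delta_a < 0 || fv$ratio_13 < 0 || fv$delta_t1_ms < 0 ||
      fv$delta_t2_s < 0 || fv$ts_s < 0 || fv$ts_s > 4 + 1e-9 || fv$vmax < 0) {
    feature_error("extracted feature vector violates its range invariants")
  }
  invisible(fv)
}

#' Preprocess and extract features for a set of recordings
#'
#' @param recordings List of [reflex_recording()] objects with labels.
#' @param config A [pipeline_config()].
#' @return A `labeled_feature_table` with one row per recording.
#' @export
extract_dataset_features <- function(recordings, config = pipeline_config()) {
  rows <- lapply(recordings, function(rec) {
    fv <- extract_features(preprocess_recording(rec, config), config)
    cbind(data.frame(subject_id = rec$subject_id,
                     label = if (is.null(rec$label)) NA_character_ else rec$label,
                     stringsAsFactors = FALSE),
          fv[, FEATURE_COLS])
  })
  df <- do.call(rbind, rows)
  labeled_feature_table(df$subject_id, df$label, df[, FEATURE_COLS])
}
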