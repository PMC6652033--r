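# Core recording container and NINDS label handling.

#' NINDS reflex grades handled by the package
#'
#' The National Institute of Neurological Disorders and Stroke scale rates a
#' deep-tendon reflex from absent (`0+`) to markedly enhanced (`4+`). The `4+`
#' grade is not represented in the cohort this package models and is rejected
#' wherever labels are validated.
#'
#' @return Character vector of the four supported grades, ordered from absent
#'   to upper-normal.
#' @export
ninds_levels <- function() c("0+", "1+", "2+", "3+")

validate_ninds_label <- function(label) {
  if (is.null(label)) return(NULL)
  label <- as.character(label)
  if (length(label) != 1L || !label %in% ninds_levels()) {
    format_error(sprintf(
      "invalid NINDS label '%s' (supported: %s; the 4+ grade is not represented)",
      paste(label, collapse = ","), paste(ninds_levels(), collapse = ", ")))
  }
  label
}

ninds_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), ninds_levels())
  if (length(bad) > 0L) {
    format_error(sprintf(
      "invalid NINDS label(s): %s (supported: %s)",
      paste(bad, collapse = ", "), paste(ninds_levels(), collapse = ", ")))
  }
  factor(labels, levels = ninds_levels())
}

#' Construct a three-channel reflex recording
#'
#' A recording holds the three synchronised channels captured during a
#' patellar-reflex test: the piezoelectric impact pulse (volts), the knee
#' angular position (degrees) and the knee angular velocity (degrees/s),
#' uniformly sampled from time zero.
#'
#' @param impact Numeric vector, impact-sensor channel in volts.
#' @param angle Numeric vector, angular position in degrees.
#' @param velocity Numeric vector, angular velocity in degrees/s.
#' @param sample_rate Sampling rate in Hz (default 5000).
#' @param subject_id Opaque subject identifier string.
#' @param label Optional NINDS grade, one of `ninds_levels()`.
#' @param time Optional time vector in seconds; defaults to a uniform grid
#'   starting at 0. If supplied it must be uniform at `1/sample_rate` within
#'   1e-9 s.
#'
#' @return An object of class `reflex_recording`.
#' @export
reflex_recording <- function(impact, angle, velocity, sample_rate = 5000,
                             subject_id = "anonymous", label = NULL,
                             time = NULL) {
  n <- length(impact)
  if (n < 1L) usage_error("a recording needs at least one sample")
  if (length(angle) != n || length(velocity) != n) {
    usage_error("impact, angle and velocity channels must have identical length")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    usage_error("sample_rate must be a single positive number")
  }
  if (is.null(time)) {
    time <- (seq_len(n) - 1) / sample_rate
  } else {
    if (length(time) != n) usage_error("time vector length mismatch")
    if (n > 1L) {
      dt <- diff(time)
      if (max(abs(dt - 1 / sample_rate)) > 1e-9) {
        usage_error("time vector is not uniform at 1/sample_rate within 1e-9 s")
      }
    }
  }
  label <- validate_ninds_label(label)
  structure(
    list(time = as.numeric(time), impact = as.numeric(impact),
         angle = as.numeric(angle), velocity = as.numeric(velocity),
         sample_rate = sample_rate, subject_id = as.character(subject_id),
         label = label),
    class = "reflex_recording")
}

#' @export
print.reflex_recording <- function(x, ...) {
  cat(sprintf(
    "<reflex_recording> %s%s: %d samples @ %g Hz (%.3f s)\n",
    x$subject_id,
    if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
    length(x$angle), x$sample_rate, length(x$angle) / x$sample_rate))
  invisible(x)
}

n_samples <- function(rec) length(rec$angle)
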