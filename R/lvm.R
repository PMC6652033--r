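# Reading and writing recordings in a minimal LVM (LabVIEW measurement) text
# dialect: a tab-separated key/value header block terminated by
# ***End_of_Header***, a tab-separated column-name line, then numeric rows.
# Channel identity is taken from the column names, never from position.

LVM_TERMINATOR <- "***End_of_Header***"

lvm_colname_map <- c(
  "x_value" = "time", "time" = "time",
  "impact" = "impact", "angle" = "angle", "velocity" = "velocity")

#' Read a reflex recording from an LVM-dialect text file
#'
#' The reader expects a header block of tab-separated `key<TAB>value` lines
#' terminated by `***End_of_Header***`, followed by a tab-separated column
#' header naming the four channels (`X_Value`/`Time`, `Impact`, `Angle`,
#' `Velocity`, any order, case-insensitive) and one numeric row per sample.
#' The sample rate is taken from a `Sample_Rate` header field when present,
#' otherwise inferred from the first two time stamps. Comma decimal separators
#' are rejected explicitly rather than guessed at.
#'
#' @param path Path to the file.
#' @return A [reflex_recording()].
#' @export
read_lvm <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  term <- which(lines == LVM_TERMINATOR)
  if (length(term) == 0L) {
    format_error(sprintf("missing '%s' header terminator in %s",
                         LVM_TERMINATOR, path))
  }
  term <- term[1L]
  header <- list()
  for (ln in lines[seq_len(term - 1L)]) {
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) >= 2L) header[[tolower(parts[1L])]] <- parts[2L]
  }

  body <- lines[seq.int(term + 1L, length(lines))]
  body_idx <- seq.int(term + 1L, length(lines))  # original line numbers
  keep <- nzchar(trimws(body))
  body <- body[keep]
  body_idx <- body_idx[keep]
  if (length(body) < 2L) format_error("no column header / data rows after header block")

  cols <- tolower(trimws(strsplit(body[1L], "\t", fixed = TRUE)[[1L]]))
  known <- lvm_colname_map[cols]
  if (anyNA(known)) {
    format_error(sprintf("unrecognised column name(s): %s",
                         paste(cols[is.na(known)], collapse = ", ")))
  }
  need <- c("time", "impact", "angle", "velocity")
  if (!setequal(known, need)) {
    format_error(sprintf("expected columns %s; found %s",
                         paste(need, collapse = ","), paste(known, collapse = ",")))
  }

  rows <- body[-1L]
  row_idx <- body_idx[-1L]
  if (any(grepl(",", rows, fixed = TRUE))) {
    bad <- row_idx[grepl(",", rows, fixed = TRUE)][1L]
    format_error(sprintf(
      "comma found in data (line %d): comma-decimal locales are not supported", bad))
  }
  split_rows <- strsplit(rows, "\t", fixed = TRUE)
  ncol_ok <- lengths(split_rows) == length(cols)
  if (!all(ncol_ok)) {
    format_error(sprintf("wrong number of fields at line %d",
                         row_idx[which(!ncol_ok)[1L]]))
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(split_rows))),
                ncol = length(cols), byrow = TRUE)
  if (anyNA(mat)) {
    bad_row <- which(apply(is.na(mat), 1L, any))[1L]
    format_error(sprintf("non-numeric value at line %d", row_idx[bad_row]))
  }
  colnames(mat) <- known

  tm <- mat[, "time"]
  if (length(tm) > 1L) {
    dt <- diff(tm)
    if (max(dt) - min(dt) > 1e-6 || any(dt <= 0)) {
      format_error("non-uniform time step (jitter exceeds 1e-6 s)")
    }
  }

  sr <- header[["sample_rate"]]
  if (!is.null(sr)) {
    sample_rate <- as.numeric(sr)
    if (!is.finite(sample_rate) || sample_rate <= 0) {
      format_error("invalid Sample_Rate header value")
    }
  } else if (length(tm) > 1L) {
    sample_rate <- 1 / (tm[2L] - tm[1L])
    # snap to integer rates written at finite precision
    if (abs(sample_rate - round(sample_rate)) < 1e-6 * sample_rate) {
      sample_rate <- round(sample_rate)
    }
  } else {
    format_error("single-sample file without a Sample_Rate header field")
  }

  label <- header[["label"]]
  if (!is.null(label)) label <- validate_ninds_label(label)
  subject <- header[["subject_id"]]
  if (is.null(subject)) subject <- sub("\\.lvm$", "", basename(path))

  reflex_recording(impact = mat[, "impact"], angle = mat[, "angle"],
                   velocity = mat[, "velocity"], sample_rate = sample_rate,
                   subject_id = subject, label = label)
}

#' Write a reflex recording as an LVM-dialect text file
#'
#' Emits the header block (sample rate, subject id, label when present), the
#' `***End_of_Header***` terminator, a tab-separated column header and one row
#' per sample at 15 significant digits, UTF-8 with LF line endings.
#'
#' @param recording A [reflex_recording()].
#' @param path Output path.
#' @param extra_header Optional named character vector of additional header
#'   fields (e.g. `c(Trimmed = "true")`).
#' @return Invisibly, `path`.
#' @export
write_lvm <- function(recording, path, extra_header = NULL) {
  if (!inherits(recording, "reflex_recording")) {
    usage_error("`recording` must be a reflex_recording")
  }
  hdr <- c(
    "LabVIEW_Measurement\treflexquant",
    sprintf("Sample_Rate\t%.15g", recording$sample_rate),
    sprintf("Subject_ID\t%s", recording$subject_id),
    if (!is.null(recording$label)) sprintf("Label\t%s", recording$label),
    "Decimal_Separator\t.",
    if (!is.null(extra_header)) sprintf("%s\t%s", names(extra_header), extra_header),
    LVM_TERMINATOR,
    "X_Value\tImpact\tAngle\tVelocity")
  rows <- sprintf("%.15g\t%.15g\t%.15g\t%.15g",
                  recording$time, recording$impact,
                  recording$angle, recording$velocity)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) io_error(sprintf("cannot open '%s' for writing", path)),
                  warning = function(w) io_error(sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  writeLines(c(hdr, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
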