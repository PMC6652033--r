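# Labeled feature tables: one row per recording with the six biomechanical
# features plus subject id and NINDS grade. Stored as CSV with a fixed header.

FEATURE_COLS <- c("delta_a", "ratio_13", "delta_t1_ms", "delta_t2_s",
                  "ts_s", "vmax")
TABLE_COLS <- c("subject_id", "label", FEATURE_COLS)

#' Assemble a labeled feature table
#'
#' @param subject_id Character vector of unique subject identifiers.
#' @param label NINDS grades (`ninds_levels()`).
#' @param features Data frame or matrix with the six feature columns
#'   `delta_a`, `ratio_13`, `delta_t1_ms`, `delta_t2_s`, `ts_s`, `vmax`.
#' @return A `data.frame` of class `labeled_feature_table`.
#' @export
labeled_feature_table <- function(subject_id, label, features) {
  features <- as.data.frame(features)
  if (!all(FEATURE_COLS %in% names(features))) {
    usage_error(sprintf("features must contain columns: %s",
                        paste(FEATURE_COLS, collapse = ", ")))
  }
  tbl <- data.frame(subject_id = as.character(subject_id),
                    label = ninds_factor(label),
                    features[, FEATURE_COLS, drop = FALSE],
                    stringsAsFactors = FALSE, row.names = NULL)
  validate_feature_table(tbl)
}

validate_feature_table <- function(tbl) {
  if (nrow(tbl) < 1L) format_error("feature table must have at least one row")
  if (anyDuplicated(tbl$subject_id)) {
    format_error(sprintf("duplicate subject_id: %s",
                         tbl$subject_id[duplicated(tbl$subject_id)][1L]))
  }
  vals <- as.matrix(tbl[, FEATURE_COLS])
  if (!all(is.finite(vals))) {
    format_error("feature table contains non-finite feature values")
  }
  class(tbl) <- c("labeled_feature_table", "data.frame")
  tbl
}

#' Read a labeled feature table from CSV
#'
#' Expects the exact header
#' `subject_id,label,delta_a,ratio_13,delta_t1_ms,delta_t2_s,ts_s,vmax`.
#' Unknown grade tokens (including `4+`) and duplicate subject ids are
#' rejected.
#'
#' @param path CSV path.
#' @return A `labeled_feature_table`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       label = "character"))
  if (!identical(names(df), TABLE_COLS)) {
    format_error(sprintf("unexpected CSV header; expected: %s",
                         paste(TABLE_COLS, collapse = ",")))
  }
  for (cc in FEATURE_COLS) {
    if (!is.numeric(df[[cc]])) {
      format_error(sprintf("non-numeric values in column '%s'", cc))
    }
  }
  labeled_feature_table(df$subject_id, df$label, df[, FEATURE_COLS])
}

#' Write a labeled feature table to CSV
#'
#' The round trip through [read_feature_table()] is lossless to better than
#' 1e-9 relative precision.
#'
#' @param table A `labeled_feature_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  table <- validate_feature_table(as.data.frame(table))
  out <- table
  out$label <- as.character(out$label)
  for (cc in FEATURE_COLS) out[[cc]] <- sprintf("%.15g", out[[cc]])
  tryCatch(
    utils::write.csv(out[, TABLE_COLS], path, row.names = FALSE, quote = FALSE),
    error = function(e) io_error(sprintf("cannot write '%s'", path)))
  invisible(path)
}
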