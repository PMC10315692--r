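# CSV table schemas and validation with row-numbered error messages.

.check_columns <- function(df, required, file) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s): %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

.check_numeric <- function(df, cols, file) {
  for (col in cols) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop(sprintf("%s: column '%s' is not numeric (first bad row: %d)",
                   file, col, if (is.na(bad)) 1L else bad), call. = FALSE)
    }
    if (any(!is.finite(df[[col]]))) {
      stop(sprintf("%s: column '%s' has non-finite value at row %d",
                   file, col, which(!is.finite(df[[col]]))[1]), call. = FALSE)
    }
  }
}

#' Read and validate a serial activity measurements table
#'
#' Schema: `patient_id`, `lesion_id`, `phase` (pre_selumetinib,
#' post_selumetinib, therapy), `isotope` (I123, I131), `time_h` (> 0,
#' strictly increasing within each lesion/phase series), `activity_MBq`
#' (>= 0), and optional `activity_sd_MBq`. Violations are reported with the
#' offending row number.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_measurements(df, file = basename(path))
}

#' Validate an in-memory measurements table
#'
#' @param df Data frame with the [read_measurements()] schema.
#' @param file Label used in error messages.
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_measurements <- function(df, file = "measurements") {
  .check_columns(df, c("patient_id", "lesion_id", "phase", "isotope",
                       "time_h", "activity_MBq"), file)
  .check_numeric(df, c("time_h", "activity_MBq"), file)
  if (any(df$time_h <= 0)) {
    stop(sprintf("%s: non-positive time_h at row %d", file,
                 which(df$time_h <= 0)[1]), call. = FALSE)
  }
  if (any(df$activity_MBq < 0)) {
    stop(sprintf("%s: negative activity_MBq at row %d", file,
                 which(df$activity_MBq < 0)[1]), call. = FALSE)
  }
  bad_iso <- !df$isotope %in% c("I123", "I131")
  if (any(bad_iso)) {
    stop(sprintf("%s: unknown isotope '%s' at row %d", file,
                 df$isotope[bad_iso][1], which(bad_iso)[1]), call. = FALSE)
  }
  key <- paste(df$lesion_id, df$phase, sep = "\r")
  for (grp in split(seq_len(nrow(df)), key)) {
    tt <- df$time_h[grp]
    if (anyDuplicated(tt)) {
      stop(sprintf("%s: duplicate (lesion_id, phase, time_h) key at row %d",
                   file, grp[which(duplicated(tt))[1]]), call. = FALSE)
    }
    if (is.unsorted(tt, strictly = TRUE)) {
      stop(sprintf("%s: out-of-order times within series at row %d",
                   file, grp[which(diff(tt) < 0)[1] + 1L]), call. = FALSE)
    }
  }
  df
}

#' Read and validate a lesion table
#'
#' Schema: `lesion_id`, `patient_id`, `site`, `volume_cm3` (> 0),
#' `longest_axis_mm` (> 0).
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_lesions <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  file <- basename(path)
  .check_columns(df, c("lesion_id", "patient_id", "site", "volume_cm3",
                       "longest_axis_mm"), file)
  .check_numeric(df, c("volume_cm3", "longest_axis_mm"), file)
  if (any(df$volume_cm3 <= 0)) {
    stop(sprintf("%s: non-positive volume_cm3 at row %d", file,
                 which(df$volume_cm3 <= 0)[1]), call. = FALSE)
  }
  if (any(df$longest_axis_mm <= 0)) {
    stop(sprintf("%s: non-positive longest_axis_mm at row %d", file,
                 which(df$longest_axis_mm <= 0)[1]), call. = FALSE)
  }
  if (anyDuplicated(df$lesion_id)) {
    stop(sprintf("%s: duplicate lesion_id at row %d", file,
                 which(duplicated(df$lesion_id))[1]), call. = FALSE)
  }
  df
}

#' Read and validate a lesion response table
#'
#' Schema: `lesion_id`, `baseline_mm` (> 0), `followup_mm` (>= 0).
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  file <- basename(path)
  .check_columns(df, c("lesion_id", "baseline_mm", "followup_mm"), file)
  .check_numeric(df, c("baseline_mm", "followup_mm"), file)
  if (any(df$baseline_mm <= 0)) {
    stop(sprintf("%s: non-positive baseline_mm at row %d", file,
                 which(df$baseline_mm <= 0)[1]), call. = FALSE)
  }
  if (any(df$followup_mm < 0)) {
    stop(sprintf("%s: negative followup_mm at row %d", file,
                 which(df$followup_mm < 0)[1]), call. = FALSE)
  }
  df
}
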