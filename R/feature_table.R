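# FeatureTable container and CSV input/output.

#' Construct a patients-by-features radiomic feature table
#'
#' @param values Numeric matrix, one row per patient, one column per feature.
#'   Column names must match `meta$feature_id` (in order).
#' @param patient_ids Character vector of unique patient identifiers, one per
#'   row of `values`.
#' @param meta Feature metadata data frame with columns `feature_id`,
#'   `source_series`, `group` (see [build_feature_catalog()]).
#' @param normalization_tag One of `"RAW"`, `"ZSCORE"`, `"LRM"`.
#'
#' @return An object of class `feature_table`: a list with elements
#'   `patient_ids`, `meta`, `values` and `normalization_tag`.
#' @export
feature_table <- function(values, patient_ids, meta,
                          normalization_tag = c("RAW", "ZSCORE", "LRM")) {
  normalization_tag <- match.arg(normalization_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  patient_ids <- as.character(patient_ids)
  validate_feature_meta(meta)
  if (nrow(values) != length(patient_ids))
    stop("values has ", nrow(values), " rows but ", length(patient_ids),
         " patient ids were given")
  if (ncol(values) != nrow(meta))
    stop("values has ", ncol(values), " columns but metadata describes ",
         nrow(meta), " features")
  if (anyDuplicated(patient_ids))
    stop("duplicate patient ids: ",
         paste(unique(patient_ids[duplicated(patient_ids)]), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite feature value at patient '", patient_ids[bad[1]],
         "', feature '", meta$feature_id[bad[2]], "'")
  }
  dimnames(values) <- list(patient_ids, meta$feature_id)
  structure(list(patient_ids = patient_ids,
                 meta = as.data.frame(meta),
                 values = values,
                 normalization_tag = normalization_tag),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", length(x$patient_ids), " patients x ",
      nrow(x$meta), " features [", x$normalization_tag, "]\n", sep = "")
  cat("  series: ",
      paste(sprintf("%s (%d)", names(table(x$meta$source_series)),
                    table(x$meta$source_series)), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Drop shape features from a feature table
#'
#' Shape features describe mask geometry and are strongly linked to tumor
#' volume and outcome; clustering and survival modelling operate on the
#' grayscale features only.
#'
#' @param table A [feature_table()].
#' @return A `feature_table` without `SHAPE` features.
#' @export
drop_shape_features <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  keep <- table$meta$group != "SHAPE"
  feature_table(table$values[, keep, drop = FALSE], table$patient_ids,
                table$meta[keep, , drop = FALSE], table$normalization_tag)
}

#' Read a feature table and its metadata from CSV
#'
#' The value file has a header of feature ids with a leading `patient_id`
#' column; the metadata file maps `feature_id` to `source_series` and `group`.
#' Comma separators, `.` decimal and UTF-8 encoding are assumed.
#'
#' @param path Path to the patients-by-features CSV.
#' @param meta_path Path to the feature metadata CSV.
#' @param normalization_tag Tag recorded on the returned table.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, meta_path,
                               normalization_tag = "RAW") {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (names(raw)[1] != "patient_id")
    stop("first column of ", path, " must be 'patient_id', found '",
         names(raw)[1], "'")
  meta <- utils::read.csv(meta_path, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- setdiff(names(raw)[-1], meta$feature_id)
  if (length(need))
    stop("no metadata for feature column(s): ", paste(need, collapse = ", "))
  meta <- meta[match(names(raw)[-1], meta$feature_id), , drop = FALSE]

  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric or missing cell in ", path, " at row ", bad[1],
         " (patient '", raw$patient_id[bad[1]], "'), column '",
         names(raw)[-1][bad[2]], "'")
  }
  feature_table(num, raw$patient_id, meta, normalization_tag)
}

#' Write a feature table (and optionally its metadata) to CSV
#'
#' Round-trips with [read_feature_table()].
#'
#' @param table A [feature_table()].
#' @param path Output CSV path for the value matrix.
#' @param meta_path Optional output path for the feature metadata CSV.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, meta_path = NULL) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(patient_id = table$patient_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(table$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  if (!is.null(meta_path))
    utils::write.csv(table$meta, meta_path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read disease-specific survival records from CSV
#'
#' Expects columns `patient_id`, `time_months` (positive follow-up time) and
#' `event` (1 = death from disease, 0 = censored).
#'
#' @param path CSV path.
#' @return A data frame of class `survival_records` with columns
#'   `patient_id`, `time` (months) and `event` (logical).
#' @export
read_survival <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- setdiff(c("patient_id", "time_months", "event"), names(df))
  if (length(need))
    stop("survival CSV ", path, " missing column(s): ",
         paste(need, collapse = ", "))
  survival_records(df$patient_id, df$time_months, df$event)
}

#' Construct validated survival records
#'
#' @param patient_id Character vector of unique patient ids.
#' @param time Positive follow-up times in months.
#' @param event Event indicators in `{0, 1}` (or logical); 1 = death from
#'   disease.
#' @return A data frame of class `survival_records`.
#' @export
survival_records <- function(patient_id, time, event) {
  patient_id <- as.character(patient_id)
  time <- as.numeric(time)
  if (anyDuplicated(patient_id))
    stop("duplicate patient ids in survival records: ",
         paste(unique(patient_id[duplicated(patient_id)]), collapse = ", "))
  if (length(time) && (anyNA(time) || any(time <= 0)))
    stop("survival time must be > 0; offending patients: ",
         paste(patient_id[is.na(time) | time <= 0], collapse = ", "))
  if (is.logical(event)) event <- as.integer(event)
  if (length(event) && !all(event %in% c(0, 1)))
    stop("event indicator must be 0 or 1; offending patients: ",
         paste(patient_id[!event %in% c(0, 1)], collapse = ", "))
  structure(data.frame(patient_id = patient_id, time = time,
                       event = as.logical(event),
                       stringsAsFactors = FALSE),
            class = c("survival_records", "data.frame"))
}

#' Write survival records to CSV
#'
#' @param records A [survival_records()] data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(records, path) {
  utils::write.csv(
    data.frame(patient_id = records$patient_id,
               time_months = records$time,
               event = as.integer(records$event)),
    path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
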