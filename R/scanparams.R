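# MRI acquisition parameters: extraction from DICOM attribute maps or CSV,
# derived covariates, and design matrices for the per-feature regression.

.SCAN_SERIES <- c("VIBE+C", "T2", "DWI")

# primary per-series parameters; b_values stored as ";"-joined string so the
# table round-trips through plain CSV
.SCAN_COLS <- c("patient_id", "series_type", "spacing", "matrix_size", "tr",
                "te", "fa", "slice_thickness", "interslice_gap", "num_slices",
                "field_strength", "num_averages", "phase_encoding", "b_values")

#' Construct a table of per-series MRI acquisition parameters
#'
#' One row per patient per MRI series. Units follow the DICOM header: spacing
#' and slice thickness in mm, TR/TE in ms, flip angle in degrees, field
#' strength in tesla, b-values in s/mm^2 (stored as a `;`-joined string, DWI
#' rows only). `num_averages` may be `NA` for VIBE+C rows, where it is not
#' used as a predictor.
#'
#' @param df Data frame with columns `patient_id`, `series_type`
#'   (`"VIBE+C"`, `"T2"`, `"DWI"`), `spacing`, `matrix_size`, `tr`, `te`,
#'   `fa`, `slice_thickness`, `interslice_gap`, `num_slices`,
#'   `field_strength`, `num_averages`, `phase_encoding` (`"ROW"`/`"COLUMN"`)
#'   and `b_values`.
#' @return The validated data frame with class `scan_params`.
#' @export
scan_params <- function(df) {
  need <- setdiff(.SCAN_COLS, names(df))
  if (length(need))
    stop("scan parameter table missing column(s): ",
         paste(need, collapse = ", "))
  df <- as.data.frame(df)[, .SCAN_COLS]
  bad <- !df$series_type %in% .SCAN_SERIES
  if (any(bad))
    stop("unknown series_type: ", paste(unique(df$series_type[bad]),
                                        collapse = ", "))
  if (anyDuplicated(df[, c("patient_id", "series_type")]))
    stop("more than one record for the same patient and series")
  num_pos <- function(col, strict = TRUE) {
    v <- df[[col]]
    bad <- !is.na(v) & (if (strict) v <= 0 else v < 0)
    if (any(bad))
      stop("`", col, "` must be ", if (strict) "> 0" else ">= 0",
           "; offending patients: ",
           paste(df$patient_id[bad], collapse = ", "))
  }
  num_pos("spacing"); num_pos("matrix_size"); num_pos("slice_thickness")
  num_pos("num_slices"); num_pos("field_strength")
  num_pos("interslice_gap", strict = FALSE)
  pe_bad <- !is.na(df$phase_encoding) & !df$phase_encoding %in% c("ROW", "COLUMN")
  if (any(pe_bad))
    stop("phase_encoding must be ROW or COLUMN")
  is_dwi <- df$series_type == "DWI"
  has_b <- !is.na(df$b_values) & nzchar(df$b_values)
  if (any(is_dwi & !has_b))
    stop("DWI records must carry b_values; offending patients: ",
         paste(df$patient_id[is_dwi & !has_b], collapse = ", "))
  if (any(!is_dwi & has_b))
    stop("b_values given for non-DWI records: ",
         paste(df$patient_id[!is_dwi & has_b], collapse = ", "))
  class(df) <- c("scan_params", "data.frame")
  df
}

parse_bvalues <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}

#' Map a DICOM header attribute set to a scan-parameter record
#'
#' Consumes a named list of standard DICOM attribute values, as produced by
#' any header extractor: `PixelSpacing` (length 2, must be equal in x and y),
#' `Rows`, `RepetitionTime`, `EchoTime`, `FlipAngle`, `SliceThickness`,
#' `SpacingBetweenSlices` (optional; the interslice gap is
#' `SpacingBetweenSlices - SliceThickness`, clipped at 0) or
#' `InterSliceGap`, `NumberOfSlices`, `MagneticFieldStrength`,
#' `NumberOfAverages` (optional for VIBE+C), `InPlanePhaseEncodingDirection`
#' (`"ROW"`/`"COL"`/`"COLUMN"`), and `DiffusionBValues` (numeric vector over
#' the DWI volumes).
#'
#' @param header Named list of DICOM attribute values.
#' @param patient_id Patient identifier to record.
#' @param series_type `"VIBE+C"`, `"T2"` or `"DWI"`.
#' @return A one-row [scan_params()] table.
#' @export
parse_dicom_params <- function(header, patient_id,
                               series_type = c("VIBE+C", "T2", "DWI")) {
  series_type <- match.arg(series_type)
  get <- function(tag, mandatory = TRUE) {
    v <- header[[tag]]
    if (is.null(v)) {
      if (mandatory) stop("missing mandatory DICOM attribute '", tag, "'")
      return(NA_real_)
    }
    v
  }
  ps <- get("PixelSpacing")
  if (length(ps) == 1L) ps <- c(ps, ps)
  if (abs(ps[1] - ps[2]) > 1e-9)
    stop("PixelSpacing differs in x and y (", ps[1], " vs ", ps[2],
         "); in-plane spacing is assumed isotropic")
  st <- as.numeric(get("SliceThickness"))
  ig <- header[["InterSliceGap"]]
  if (is.null(ig)) {
    sbs <- header[["SpacingBetweenSlices"]]
    ig <- if (is.null(sbs)) 0 else max(0, as.numeric(sbs) - st)
  }
  pe <- header[["InPlanePhaseEncodingDirection"]]
  pe <- if (is.null(pe)) NA_character_
        else if (toupper(pe) %in% c("COL", "COLUMN")) "COLUMN" else "ROW"
  bv <- header[["DiffusionBValues"]]
  if (series_type == "DWI") {
    if (is.null(bv)) stop("missing mandatory DICOM attribute 'DiffusionBValues'")
    bv <- paste(sort(unique(as.numeric(bv))), collapse = ";")
  } else bv <- NA_character_
  scan_params(data.frame(
    patient_id = patient_id, series_type = series_type,
    spacing = as.numeric(ps[1]), matrix_size = as.numeric(get("Rows")),
    tr = as.numeric(get("RepetitionTime")), te = as.numeric(get("EchoTime")),
    fa = as.numeric(get("FlipAngle")), slice_thickness = st,
    interslice_gap = as.numeric(ig),
    num_slices = as.numeric(get("NumberOfSlices")),
    field_strength = as.numeric(get("MagneticFieldStrength")),
    num_averages = as.numeric(get("NumberOfAverages", mandatory = FALSE)),
    phase_encoding = pe, b_values = bv,
    stringsAsFactors = FALSE))
}

#' Read / write scan-parameter tables as CSV
#'
#' @param path CSV path (columns as in [scan_params()]).
#' @return For `read_scan_params`, a `scan_params` table.
#' @export
read_scan_params <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(b_values = "character"),
                        fileEncoding = "UTF-8")
  scan_params(df)
}

#' @rdname read_scan_params
#' @param params A [scan_params()] table.
#' @export
write_scan_params <- function(params, path) {
  utils::write.csv(params, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Derive secondary acquisition covariates
#'
#' Computes, per record: voxel volume `h^2 * ST` (mm^3), anisotropy `h / ST`,
#' field of view `(h * m)^2 * (ST + IG) * NoS` (mm^3) and, for DWI records,
#' the highest b-value and the number of b-values. A highest b-value outside
#' \[800, 4000\] s/mm^2 triggers a warning (the range observed in clinical
#' pelvic DWI protocols).
#'
#' @param params A [scan_params()] table (or one-row record).
#' @return Data frame with columns `patient_id`, `series_type`,
#'   `voxel_volume`, `anisotropy`, `field_of_view`, `high_b`, `n_bvalues`.
#' @export
derive_secondary <- function(params) {
  stopifnot(inherits(params, "scan_params"))
  h <- params$spacing; st <- params$slice_thickness
  out <- data.frame(
    patient_id = params$patient_id,
    series_type = params$series_type,
    voxel_volume = h^2 * st,
    anisotropy = h / st,
    field_of_view = (h * params$matrix_size)^2 *
      (st + params$interslice_gap) * params$num_slices,
    high_b = NA_real_, n_bvalues = NA_real_,
    stringsAsFactors = FALSE)
  is_dwi <- params$series_type == "DWI"
  if (any(is_dwi)) {
    bl <- lapply(params$b_values[is_dwi], parse_bvalues)
    out$high_b[is_dwi] <- vapply(bl, max, 0)
    out$n_bvalues[is_dwi] <- vapply(bl, length, 0L)
    oob <- out$high_b[is_dwi] < 800 | out$high_b[is_dwi] > 4000
    if (any(oob))
      warning("highest b-value outside [800, 4000] s/mm^2 for patient(s): ",
              paste(out$patient_id[is_dwi][oob], collapse = ", "))
  }
  out
}

# which acquisition series provides covariates for a feature series
covariate_series_for <- function(target_series, segmentation_series) {
  switch(target_series,
         "VIBE+C" = "VIBE+C", "T2" = "T2",
         "ADC" = "DWI", "HIGHB" = "DWI",
         "SHAPE" = {
           if (is.null(segmentation_series))
             stop("target SHAPE requires `segmentation_series`")
           if (!segmentation_series %in% c("VIBE+C", "T2"))
             stop("segmentation_series must be VIBE+C or T2")
           segmentation_series
         },
         stop("unknown target series '", target_series, "'"))
}

#' Build the regression design matrix for one feature series
#'
#' Assembles, per patient, the primary and derived acquisition covariates of
#' the series that generated the features: voxel volume, anisotropy, TR, TE,
#' flip angle, field of view, number of averages, slice thickness, field
#' strength and phase-encoding direction (COLUMN = 0, ROW = 1), plus highest
#' b-value and number of b-values for ADC / high-b targets. DWI parameters
#' serve both ADC- and high-b-derived features; shape features use the
#' segmentation series' parameters. The number of averages is dropped for
#' VIBE+C targets (constant across VIBE+C protocols). Columns constant across
#' patients are dropped with a message.
#'
#' @param params A [scan_params()] table covering all patients.
#' @param patient_ids Patient order the matrix rows must follow (matching the
#'   companion feature table).
#' @param target_series `"VIBE+C"`, `"T2"`, `"ADC"`, `"HIGHB"` or `"SHAPE"`.
#' @param segmentation_series Series whose parameters govern shape features
#'   (`"VIBE+C"` or `"T2"`); required when `target_series = "SHAPE"`.
#' @param impute_missing Median-impute missing covariate values (with a
#'   message) instead of failing (default `FALSE`).
#' @return An object of class `design_matrix`: list with `patient_ids`,
#'   numeric matrix `X` (patients x predictors) and `target_series`.
#' @export
build_design_matrix <- function(params, patient_ids, target_series,
                                segmentation_series = NULL,
                                impute_missing = FALSE) {
  stopifnot(inherits(params, "scan_params"))
  src <- covariate_series_for(target_series, segmentation_series)
  rec <- params[params$series_type == src, , drop = FALSE]
  idx <- match(patient_ids, rec$patient_id)
  if (anyNA(idx))
    stop("no ", src, " parameter record for patient(s): ",
         paste(patient_ids[is.na(idx)], collapse = ", "))
  rec <- rec[idx, , drop = FALSE]
  der <- derive_secondary(scan_params(rec))

  X <- cbind(
    voxel_volume = der$voxel_volume,
    anisotropy = der$anisotropy,
    tr = rec$tr, te = rec$te, fa = rec$fa,
    field_of_view = der$field_of_view,
    num_averages = rec$num_averages,
    slice_thickness = rec$slice_thickness,
    field_strength = rec$field_strength,
    phase_encoding = as.numeric(rec$phase_encoding == "ROW"))
  if (src == "VIBE+C")  # number of averages is constant across VIBE+C series
    X <- X[, colnames(X) != "num_averages", drop = FALSE]
  if (target_series %in% c("ADC", "HIGHB"))
    X <- cbind(X, high_b = der$high_b, n_bvalues = der$n_bvalues)

  if (anyNA(X)) {
    if (impute_missing) {
      n_imp <- sum(is.na(X))
      for (j in seq_len(ncol(X))) {
        miss <- is.na(X[, j])
        if (any(miss)) X[miss, j] <- stats::median(X[, j], na.rm = TRUE)
      }
      message("build_design_matrix: median-imputed ", n_imp,
              " missing covariate value(s) for target ", target_series)
    } else {
      bad <- colnames(X)[colSums(is.na(X)) > 0]
      stop("missing covariate value(s) in column(s): ",
           paste(bad, collapse = ", "),
           " (set impute_missing = TRUE to median-impute)")
    }
  }

  const <- apply(X, 2, function(v) max(v) - min(v) == 0)
  if (any(const)) {
    message("build_design_matrix: dropping constant column(s) for target ",
            target_series, ": ", paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  rownames(X) <- patient_ids
  structure(list(patient_ids = patient_ids, X = X,
                 target_series = target_series),
            class = "design_matrix")
}

#' Per-patient scanning-parameter table for enrichment testing
#'
#' Joins the primary parameters of one acquisition series with its derived
#' covariates into a per-patient data frame, typed so that enrichment testing
#' can dispatch Kruskal-Wallis (continuous) vs chi-square (categorical)
#' tests. `phase_encoding` is categorical; everything else continuous.
#'
#' @inheritParams build_design_matrix
#' @param series Acquisition series (`"VIBE+C"`, `"T2"` or `"DWI"`).
#' @return Data frame, one row per patient, first column `patient_id`.
#' @export
scan_param_table <- function(params, patient_ids, series) {
  stopifnot(inherits(params, "scan_params"), series %in% .SCAN_SERIES)
  rec <- params[params$series_type == series, , drop = FALSE]
  idx <- match(patient_ids, rec$patient_id)
  if (anyNA(idx))
    stop("no ", series, " parameter record for patient(s): ",
         paste(patient_ids[is.na(idx)], collapse = ", "))
  rec <- rec[idx, , drop = FALSE]
  der <- derive_secondary(scan_params(rec))
  out <- data.frame(
    patient_id = rec$patient_id,
    spacing = rec$spacing, matrix_size = rec$matrix_size,
    tr = rec$tr, te = rec$te, fa = rec$fa,
    slice_thickness = rec$slice_thickness,
    interslice_gap = rec$interslice_gap, num_slices = rec$num_slices,
    field_strength = rec$field_strength, num_averages = rec$num_averages,
    phase_encoding = rec$phase_encoding,
    voxel_volume = der$voxel_volume, anisotropy = der$anisotropy,
    field_of_view = der$field_of_view,
    stringsAsFactors = FALSE)
  if (series == "DWI") {
    out$high_b <- der$high_b
    out$n_bvalues <- der$n_bvalues
  }
  out
}
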