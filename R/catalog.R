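# Frozen radiomic feature catalog.
#
# Grayscale feature names follow the IBSI-aligned nomenclature used by common
# extraction software; the per-group counts (GLCM 24, GLRLM 16, GLDM 14,
# GLSZM 16, NGTDM 5, first-order 18 => 93 per series; 13 shape features) are
# frozen here so catalog sizes are stable regardless of any extraction
# library's defaults.

.RADNORM_SERIES <- c("VIBE+C", "T2", "ADC", "HIGHB", "SHAPE")
.RADNORM_GROUPS <- c("GLCM", "GLRLM", "GLDM", "GLSZM", "NGTDM",
                     "FIRSTORDER", "SHAPE")

.RADNORM_FEATURE_NAMES <- list(
  GLCM = c(
    "Autocorrelation", "ClusterProminence", "ClusterShade",
    "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
    "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
    "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
    "JointEntropy", "MCC", "MaximumProbability", "SumAverage",
    "SumEntropy", "SumSquares"),
  GLRLM = c(
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
    "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
    "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
    "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
    "ShortRunLowGrayLevelEmphasis"),
  GLDM = c(
    "DependenceEntropy", "DependenceNonUniformity",
    "DependenceNonUniformityNormalized", "DependenceVariance",
    "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
    "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
    "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
    "SmallDependenceLowGrayLevelEmphasis"),
  GLSZM = c(
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
    "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
    "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
    "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
    "ZoneEntropy", "ZonePercentage", "ZoneVariance"),
  NGTDM = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength"),
  FIRSTORDER = c(
    "10Percentile", "90Percentile", "Energy", "Entropy",
    "InterquartileRange", "Kurtosis", "Maximum", "Mean",
    "MeanAbsoluteDeviation", "Median", "Minimum", "Range",
    "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
    "TotalEnergy", "Uniformity", "Variance"),
  SHAPE = c(
    "Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
    "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
    "Maximum2DDiameterSlice", "Maximum3DDiameter", "MeshVolume",
    "MinorAxisLength", "Sphericity", "SurfaceArea", "SurfaceVolumeRatio")
)

.GRAYSCALE_GROUPS <- c("GLCM", "GLRLM", "GLDM", "GLSZM", "NGTDM", "FIRSTORDER")

#' Build the radiomic feature catalog for a set of MRI series
#'
#' Enumerates the grayscale feature metadata for each requested source series
#' (93 features per series: 24 GLCM, 16 GLRLM, 14 GLDM, 16 GLSZM, 5 NGTDM and
#' 18 first-order) and, optionally, the 13 mask-derived shape features, which
#' are extracted once per patient and therefore appear exactly once.
#'
#' @param series Character vector of source series, a subset of
#'   `c("VIBE+C", "T2", "ADC", "HIGHB")`. Duplicates are an error.
#' @param include_shape Append the 13 shape features (`TRUE` by default)?
#'
#' @return A data frame of class `feature_meta` with columns `feature_id`
#'   (unique, `<series>_<group>_<name>`), `source_series` and `group`.
#'
#' @examples
#' nrow(build_feature_catalog(c("VIBE+C", "T2", "ADC", "HIGHB")))  # 385
#' nrow(build_feature_catalog(c("T2", "ADC", "HIGHB")))            # 292
#' nrow(build_feature_catalog("T2", include_shape = FALSE))        # 93
#' @export
build_feature_catalog <- function(series, include_shape = TRUE) {
  if (length(series) == 0L)
    stop("`series` must be non-empty")
  if (anyDuplicated(series))
    stop("duplicated entries in `series`: ",
         paste(unique(series[duplicated(series)]), collapse = ", "))
  bad <- setdiff(series, setdiff(.RADNORM_SERIES, "SHAPE"))
  if (length(bad))
    stop("unknown series (SHAPE is controlled by `include_shape`): ",
         paste(bad, collapse = ", "))

  rows <- lapply(series, function(s) {
    do.call(rbind, lapply(.GRAYSCALE_GROUPS, function(g) {
      nm <- .RADNORM_FEATURE_NAMES[[g]]
      data.frame(feature_id = paste(s, g, nm, sep = "_"),
                 source_series = s, group = g,
                 stringsAsFactors = FALSE)
    }))
  })
  cat <- do.call(rbind, rows)
  if (include_shape) {
    nm <- .RADNORM_FEATURE_NAMES$SHAPE
    cat <- rbind(cat, data.frame(
      feature_id = paste("SHAPE", "SHAPE", nm, sep = "_"),
      source_series = "SHAPE", group = "SHAPE",
      stringsAsFactors = FALSE))
  }
  rownames(cat) <- NULL
  class(cat) <- c("feature_meta", "data.frame")
  cat
}

validate_feature_meta <- function(meta) {
  stopifnot(is.data.frame(meta),
            all(c("feature_id", "source_series", "group") %in% names(meta)))
  if (anyDuplicated(meta$feature_id))
    stop("duplicate feature_id in metadata: ",
         paste(utils::head(meta$feature_id[duplicated(meta$feature_id)], 5),
               collapse = ", "))
  bad <- !meta$source_series %in% .RADNORM_SERIES
  if (any(bad))
    stop("unknown source_series: ",
         paste(unique(meta$source_series[bad]), collapse = ", "))
  bad <- !meta$group %in% .RADNORM_GROUPS
  if (any(bad))
    stop("unknown feature group: ",
         paste(unique(meta$group[bad]), collapse = ", "))
  shape_mismatch <- xor(meta$group == "SHAPE", meta$source_series == "SHAPE")
  if (any(shape_mismatch))
    stop("group SHAPE and source_series SHAPE must coincide; offending ids: ",
         paste(utils::head(meta$feature_id[shape_mismatch], 5), collapse = ", "))
  invisible(meta)
}
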