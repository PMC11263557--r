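# Shared fixtures: tiny hand-built tables and parameter sets.

# minimal feature table: n patients, p features from the T2 catalog
tiny_table <- function(n = 6, p = 3, values = NULL, seed = 42) {
  set.seed(seed)
  meta <- build_feature_catalog("T2", include_shape = FALSE)[seq_len(p), ]
  if (is.null(values)) values <- matrix(rnorm(n * p), n, p)
  feature_table(values, sprintf("P%02d", seq_len(n)), meta)
}

# hand-specified scan parameters with variation in every predictor column
varied_scan_params <- function(ids, series_type = "T2") {
  n <- length(ids)
  set.seed(7)
  scan_params(data.frame(
    patient_id = ids, series_type = series_type,
    spacing = seq(0.5, 0.8, length.out = n),
    matrix_size = rep(c(256, 320, 384), length.out = n),
    tr = seq(4000, 6000, length.out = n),
    te = seq(80, 110, length.out = n),
    fa = seq(120, 150, length.out = n),
    slice_thickness = seq(3, 4.5, length.out = n),
    interslice_gap = seq(0, 0.6, length.out = n),
    num_slices = rep(c(30, 34, 38), length.out = n),
    field_strength = rep(c(1.5, 3), length.out = n),
    num_averages = rep(c(1, 2), length.out = n),
    phase_encoding = rep(c("ROW", "COLUMN"), length.out = n),
    b_values = if (series_type == "DWI")
      rep(c("0;800", "0;100;800", "0;800;1000"), length.out = n)
      else NA_character_,
    stringsAsFactors = FALSE))
}

# small synthetic cohort for pipeline tests
small_cohort <- function(seed = 1, n = 80, p_per_series = 15, ...) {
  gen_cohort(synthetic_config(n_patients = n,
                              n_features_per_series = p_per_series,
                              seed = seed, ...))
}
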