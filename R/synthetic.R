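# Synthetic multi-scanner radiomic cohorts with known ground truth:
# protocol covariates drawn from scanner profiles, features with linear
# protocol bias, two latent patient clusters, and censored disease-specific
# survival. The generator emits the same containers the readers produce, so
# synthetic cohorts are indistinguishable from real inputs downstream.

#' Describe one scanner/protocol profile
#'
#' A profile holds, per acquisition series, the sampling distributions of the
#' primary scanning parameters: continuous parameters as `c(mean, sd)` of a
#' positive-truncated normal, matrix size and number of averages as choice
#' sets, phase encoding as the probability of ROW, and DWI b-value sets as a
#' list of candidate vectors.
#'
#' @param name Profile label (e.g. vendor/site/field strength).
#' @param weight Mixing weight (normalized across profiles).
#' @param field_strength Tesla (1.5 or 3 in the emulated cohorts).
#' @param series Named list (`"VIBE+C"`, `"T2"`, `"DWI"`) of parameter
#'   specification lists with entries `tr`, `te`, `fa`, `st`, `ig`,
#'   `spacing`, `matrix_size`, `num_slices`, `num_averages` (NA for
#'   VIBE+C), `phase_row_prob`, and `b_sets` (DWI only).
#' @return A list of class `scanner_profile`.
#' @export
scanner_profile <- function(name, weight, field_strength, series) {
  stopifnot(is.character(name), weight > 0, field_strength > 0,
            is.list(series), length(series) >= 1)
  structure(list(name = name, weight = weight,
                 field_strength = field_strength, series = series),
            class = "scanner_profile")
}

#' Configuration of a synthetic multi-scanner radiomic cohort
#'
#' @param n_patients Cohort size.
#' @param series Feature source series to generate, subset of
#'   `c("VIBE+C", "T2", "ADC", "HIGHB")`.
#' @param include_shape Also generate the 13 shape features?
#' @param segmentation_series Series whose parameters drive shape-feature
#'   bias (`"VIBE+C"` or `"T2"`).
#' @param scanner_profiles List of [scanner_profile()]s.
#' @param n_features_per_series Grayscale features per series (<= 93; ids
#'   are taken from the frozen catalog).
#' @param bias_sparsity Fraction of features with injected protocol bias.
#' @param bias_r2 Target fraction of a biased feature's variance explained
#'   by the protocol covariates (standardized effect size).
#' @param cluster_effect Latent cluster shift on informative features, in
#'   units of the noise SD.
#' @param cluster_prevalence Prevalence of latent cluster 2, in (0, 1).
#' @param informative_fraction Fraction of grayscale features carrying the
#'   cluster shift.
#' @param informative_from `"unbiased"` (default; prognostic signal is
#'   bias-independent) or `"any"`.
#' @param hazard_ratio Disease-specific hazard ratio of cluster 2 vs 1.
#' @param baseline_hazard Cluster-1 exponential hazard per month.
#' @param censor_window `c(lo, hi)` months of the uniform censoring time.
#' @param noise_sd Feature noise standard deviation.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 150L,
                             series = c("T2", "ADC"),
                             include_shape = FALSE,
                             segmentation_series = "T2",
                             scanner_profiles = default_profiles_ec(),
                             n_features_per_series = 20L,
                             bias_sparsity = 0.4,
                             bias_r2 = 0.4,
                             cluster_effect = 1.2,
                             cluster_prevalence = 0.3,
                             informative_fraction = 0.3,
                             informative_from = c("unbiased", "any"),
                             hazard_ratio = 3,
                             baseline_hazard = 0.002,
                             censor_window = c(6, 120),
                             noise_sd = 1,
                             seed = 1L) {
  informative_from <- match.arg(informative_from)
  stopifnot(n_patients >= 4, length(series) >= 1,
            all(series %in% c("VIBE+C", "T2", "ADC", "HIGHB")),
            segmentation_series %in% c("VIBE+C", "T2"),
            n_features_per_series >= 1, n_features_per_series <= 93,
            bias_sparsity >= 0, bias_sparsity <= 1,
            bias_r2 >= 0, bias_r2 < 1,
            cluster_prevalence > 0, cluster_prevalence < 1,
            informative_fraction >= 0, informative_fraction <= 1,
            hazard_ratio > 0, baseline_hazard > 0,
            length(censor_window) == 2, censor_window[1] > 0,
            censor_window[2] > censor_window[1], noise_sd > 0)
  w <- vapply(scanner_profiles, `[[`, 0, "weight")
  structure(list(n_patients = as.integer(n_patients), series = series,
                 include_shape = include_shape,
                 segmentation_series = segmentation_series,
                 scanner_profiles = scanner_profiles,
                 profile_weights = w / sum(w),
                 n_features_per_series = as.integer(n_features_per_series),
                 bias_sparsity = bias_sparsity, bias_r2 = bias_r2,
                 cluster_effect = cluster_effect,
                 cluster_prevalence = cluster_prevalence,
                 informative_fraction = informative_fraction,
                 informative_from = informative_from,
                 hazard_ratio = hazard_ratio,
                 baseline_hazard = baseline_hazard,
                 censor_window = censor_window, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

rpos <- function(n, spec) {
  v <- stats::rnorm(n, spec[1], spec[2])
  pmax(v, spec[1] * 0.2)  # keep physical parameters positive
}

sample_series_params <- function(ids, series_type, profiles, assign) {
  n <- length(ids)
  one <- function(i) {
    sp <- profiles[[assign[i]]]$series[[series_type]]
    if (is.null(sp))
      stop("profile '", profiles[[assign[i]]]$name,
           "' has no distributions for series ", series_type)
    data.frame(
      patient_id = ids[i], series_type = series_type,
      spacing = rpos(1, sp$spacing),
      matrix_size = sample(rep(sp$matrix_size, 2), 1),
      tr = rpos(1, sp$tr), te = rpos(1, sp$te), fa = rpos(1, sp$fa),
      slice_thickness = rpos(1, sp$st),
      interslice_gap = max(0, stats::rnorm(1, sp$ig[1], sp$ig[2])),
      num_slices = max(8, round(stats::rnorm(1, sp$num_slices[1],
                                             sp$num_slices[2]))),
      field_strength = profiles[[assign[i]]]$field_strength,
      num_averages = if (all(is.na(sp$num_averages))) NA_real_
                     else sample(rep(sp$num_averages, 2), 1),
      phase_encoding = if (stats::runif(1) < sp$phase_row_prob) "ROW"
                       else "COLUMN",
      b_values = if (series_type == "DWI")
        paste(sp$b_sets[[sample.int(length(sp$b_sets), 1)]], collapse = ";")
        else NA_character_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_len(n), one))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Patients are assigned to scanner profiles by the mixing weights and to two
#' latent clusters by the prevalence; per-series acquisition parameters are
#' sampled from the profile distributions; each feature follows the linear
#' model `f = b0 + X b + delta * 1[cluster 2] + eps` with Gaussian noise,
#' where `X` are the acquisition covariates of the feature's source series
#' and `b` is nonzero for a `bias_sparsity` fraction of features (scaled so
#' the covariates explain about `bias_r2` of the feature variance); shape
#' features take their covariates from the segmentation series and carry no
#' cluster effect. Disease-specific survival is exponential with hazard
#' `baseline_hazard * hazard_ratio^[cluster 2]`, censored uniformly over
#' `censor_window`. Deterministic given the configuration (generation order:
#' profiles, clusters, parameters, features, survival, censoring).
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_cohort` with elements `params`
#'   ([scan_params()]), `table` (RAW [feature_table()]), `survival`
#'   ([survival_records()]), `designs` (named list of design matrices, one
#'   per feature series), `truth` (`synthetic_ground_truth`: per-feature
#'   bias coefficients `B`, `biased_feature_ids`, `informative_feature_ids`,
#'   `cluster_labels`, `risk_score`, `profile`), and `config`.
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n <- config$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  profiles <- config$scanner_profiles
  assign <- sample.int(length(profiles), n, replace = TRUE,
                       prob = config$profile_weights)
  clusters <- 1L + stats::rbinom(n, 1L, config$cluster_prevalence)

  acq_needed <- unique(c(
    vapply(config$series, covariate_series_for, "", NULL),
    if (config$include_shape) config$segmentation_series))
  params <- scan_params(do.call(rbind, lapply(
    acq_needed, sample_series_params, ids = ids, profiles = profiles,
    assign = assign)))

  feat_series <- c(config$series, if (config$include_shape) "SHAPE")
  designs <- stats::setNames(lapply(feat_series, function(s)
    suppressMessages(build_design_matrix(
      params, ids, s, segmentation_series = config$segmentation_series))),
    feat_series)

  catalog <- build_feature_catalog(config$series,
                                   include_shape = config$include_shape)
  keep <- unlist(lapply(split(seq_len(nrow(catalog)), catalog$source_series),
                        function(ix) ix[seq_len(min(
                          length(ix),
                          if (catalog$source_series[ix[1]] == "SHAPE") 13L
                          else config$n_features_per_series))]))
  meta <- catalog[sort(keep), , drop = FALSE]

  p <- nrow(meta)
  gray <- which(meta$group != "SHAPE")
  n_biased <- round(config$bias_sparsity * p)
  biased <- sort(sample.int(p, n_biased))
  pool <- if (config$informative_from == "unbiased")
    setdiff(gray, biased) else gray
  n_inf <- min(length(pool), round(config$informative_fraction * length(gray)))
  informative <- sort(pool[sample.int(length(pool), n_inf)])

  sigma <- config$noise_sd
  cl2 <- as.numeric(clusters == 2L)
  values <- matrix(0, n, p)
  B <- vector("list", p)
  names(B) <- meta$feature_id
  for (j in seq_len(p)) {
    X <- designs[[meta$source_series[j]]]$X
    b <- stats::setNames(numeric(ncol(X)), colnames(X))
    if (j %in% biased) {
      nb <- sample(1:min(3L, ncol(X)), 1)
      sel <- sample.int(ncol(X), nb)
      g <- stats::rnorm(nb)
      eta <- X[, sel, drop = FALSE] %*% g
      v <- stats::var(as.numeric(eta))
      if (v > 0) {
        target <- config$bias_r2 / (1 - config$bias_r2) * sigma^2
        b[sel] <- g * sqrt(target / v)
      }
    }
    delta <- if (j %in% informative)
      config$cluster_effect * sigma * sample(c(-1, 1), 1) else 0
    values[, j] <- stats::rnorm(1, 0, sigma) + X %*% b + delta * cl2 +
      stats::rnorm(n, 0, sigma)
    B[[j]] <- b
    attr(B[[j]], "cluster_delta") <- delta
  }
  table <- feature_table(values, ids, meta, "RAW")

  rate <- config$baseline_hazard * config$hazard_ratio^cl2
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, config$censor_window[1], config$censor_window[2])
  surv <- survival_records(ids, pmin(t_event, t_cens), t_event <= t_cens)

  truth <- structure(list(
    B = B,
    biased_feature_ids = meta$feature_id[biased],
    informative_feature_ids = meta$feature_id[informative],
    cluster_labels = clusters,
    risk_score = log(config$hazard_ratio) * cl2,
    profile = vapply(profiles, `[[`, "", "name")[assign]),
    class = "synthetic_ground_truth")

  structure(list(params = params, table = table, survival = surv,
                 designs = designs, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> n =", x$config$n_patients, "patients,",
      nrow(x$table$meta), "features,",
      length(x$truth$biased_feature_ids), "biased,",
      sum(x$survival$event), "events\n")
  invisible(x)
}

# --- preset scanner profiles ------------------------------------------------

# single-site Siemens protocols at two field strengths (endometrial-like)
default_profiles_ec <- function() {
  vibe <- function(tr, te, fa, st, sp) list(
    tr = c(tr, 0.4), te = c(te, 0.15), fa = c(fa, 1), st = c(st, 0.2),
    ig = c(0, 0), spacing = c(sp, 0.08), matrix_size = c(256, 288, 320),
    num_slices = c(72, 6), num_averages = NA, phase_row_prob = 0.2)
  t2 <- function(tr, te, fa, st, sp) list(
    tr = c(tr, 500), te = c(te, 6), fa = c(fa, 8), st = c(st, 0.3),
    ig = c(0.35, 0.1), spacing = c(sp, 0.05), matrix_size = c(320, 384, 448),
    num_slices = c(34, 4), num_averages = c(1, 2), phase_row_prob = 0.3)
  dwi <- function(tr, te, st, sp, bsets) list(
    tr = c(tr, 700), te = c(te, 6), fa = c(90, 2), st = c(st, 0.35),
    ig = c(0.4, 0.15), spacing = c(sp, 0.15), matrix_size = c(128, 160, 192),
    num_slices = c(30, 4), num_averages = c(2, 3, 4), phase_row_prob = 0.8,
    b_sets = bsets)
  list(
    scanner_profile("siemens_1.5T", 71, 1.5, list(
      "VIBE+C" = vibe(5.2, 1.9, 10, 1.6, 1.0),
      "T2" = t2(4400, 93, 140, 3.6, 0.62),
      "DWI" = dwi(5400, 76, 4.0, 1.65,
                  list(c(0, 800), c(0, 100, 800))))),
    scanner_profile("siemens_3T", 65, 3.0, list(
      "VIBE+C" = vibe(4.1, 1.5, 9, 1.3, 0.9),
      "T2" = t2(5200, 101, 150, 3.1, 0.55),
      "DWI" = dwi(7100, 66, 3.5, 1.4,
                  list(c(0, 800), c(0, 50, 800, 1000))))))
}

# three sites / mixed vendors, wider protocol spread (cervical-like)
default_profiles_cc <- function() {
  t2 <- function(tr, te, fa, st, sp, sdmul = 1) list(
    tr = c(tr, 700 * sdmul), te = c(te, 9 * sdmul), fa = c(fa, 12),
    st = c(st, 0.45), ig = c(0.5, 0.2), spacing = c(sp, 0.09),
    matrix_size = c(256, 320, 384, 448), num_slices = c(32, 5),
    num_averages = c(1, 2, 3), phase_row_prob = 0.35)
  dwi <- function(tr, te, st, sp, bsets, sdmul = 1) list(
    tr = c(tr, 1000 * sdmul), te = c(te, 9 * sdmul), fa = c(90, 4),
    st = c(st, 0.5), ig = c(0.6, 0.25), spacing = c(sp, 0.22),
    matrix_size = c(112, 128, 160, 192), num_slices = c(28, 5),
    num_averages = c(1, 2, 4, 6), phase_row_prob = 0.7, b_sets = bsets)
  list(
    scanner_profile("ge_1.5T", 10, 1.5, list(
      "T2" = t2(4000, 88, 130, 4.0, 0.70, 1.3),
      "DWI" = dwi(5000, 82, 5.0, 1.9, list(c(0, 800), c(0, 1000)), 1.3))),
    scanner_profile("philips_1.5T", 31, 1.5, list(
      "T2" = t2(4300, 90, 125, 3.8, 0.68),
      "DWI" = dwi(5200, 78, 4.5, 1.75,
                  list(c(0, 800), c(0, 100, 1000))))),
    scanner_profile("philips_3T", 9, 3.0, list(
      "T2" = t2(5600, 104, 145, 3.2, 0.52),
      "DWI" = dwi(7600, 64, 3.6, 1.45,
                  list(c(0, 1000), c(0, 100, 1000, 2000))))),
    scanner_profile("siemens_1.5T", 54, 1.5, list(
      "T2" = t2(4500, 94, 138, 3.6, 0.62),
      "DWI" = dwi(5500, 75, 4.2, 1.65, list(c(0, 800), c(0, 100, 800))))),
    scanner_profile("siemens_3T", 28, 3.0, list(
      "T2" = t2(5300, 100, 148, 3.0, 0.55),
      "DWI" = dwi(7000, 67, 3.4, 1.4,
                  list(c(0, 800), c(0, 50, 800, 1000))))))
}

#' Preset cohort configurations emulating the two study cohorts
#'
#' `default_ec_like()` emulates a single-site endometrial-cancer-like cohort:
#' 136 patients, four feature series (VIBE+C, T2, ADC, high-b) plus shape,
#' two Siemens scanner profiles (1.5 T and 3 T), ~42% of features biased,
#' VIBE+C as segmentation series, ~15% disease-specific events over a median
#' follow-up around 60 months. `default_cc_like()` emulates a three-site
#' cervical-cancer-like cohort: 132 patients, three feature series (T2, ADC,
#' high-b) plus shape, five scanner profiles with broader protocol spread,
#' ~62% of features biased, T2 segmentation, ~25% events.
#'
#' @param seed Integer seed stored in the configuration.
#' @return A [synthetic_config()].
#' @export
default_ec_like <- function(seed = 1L) {
  synthetic_config(
    n_patients = 136L, series = c("VIBE+C", "T2", "ADC", "HIGHB"),
    include_shape = TRUE, segmentation_series = "VIBE+C",
    scanner_profiles = default_profiles_ec(),
    n_features_per_series = 93L, bias_sparsity = 0.42, bias_r2 = 0.4,
    cluster_effect = 1.2, cluster_prevalence = 0.3,
    informative_fraction = 0.3, hazard_ratio = 3.5,
    baseline_hazard = 0.002, censor_window = c(6, 120), noise_sd = 1,
    seed = seed)
}

#' @rdname default_ec_like
#' @export
default_cc_like <- function(seed = 1L) {
  synthetic_config(
    n_patients = 132L, series = c("T2", "ADC", "HIGHB"),
    include_shape = TRUE, segmentation_series = "T2",
    scanner_profiles = default_profiles_cc(),
    n_features_per_series = 93L, bias_sparsity = 0.62, bias_r2 = 0.45,
    cluster_effect = 1.2, cluster_prevalence = 0.3,
    informative_fraction = 0.3, hazard_ratio = 3,
    baseline_hazard = 0.003, censor_window = c(6, 132), noise_sd = 1,
    seed = seed)
}
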