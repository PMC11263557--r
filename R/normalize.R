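# Feature normalization: column z-scoring, per-feature multilinear regression
# against acquisition covariates, FDR-gated residualization (LRM
# normalization), and the association audit.

#' Z-score a numeric vector
#'
#' Centers to mean 0 and scales to unit sample standard deviation (n - 1
#' denominator).
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @param feature_id Optional id used in the zero-variance error message.
#' @return Numeric vector with mean 0 and sample sd 1.
#' @examples
#' zscore(c(2, 4, 6))  # -1 0 1
#' @export
zscore <- function(values, feature_id = NULL) {
  if (length(values) < 2L)
    stop("zscore needs at least 2 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("zero variance feature",
         if (!is.null(feature_id)) paste0(" '", feature_id, "'"))
  (values - mean(values)) / s
}

#' Fit the per-feature multilinear regression on acquisition covariates
#'
#' Ordinary least squares of one radiomic feature on the acquisition
#' covariates of its source series, with the overall F test of the model
#' against the intercept-only fit and per-coefficient t tests. Aliased
#' (exactly collinear) columns are assigned coefficient 0; fitted values,
#' residuals and R^2 are unaffected by that convention.
#'
#' @param f Numeric response vector (one feature over patients).
#' @param design A `design_matrix` (see [build_design_matrix()]) or a plain
#'   numeric matrix with named columns; rows must align with `f`.
#' @return An object of class `lrm_fit`: list with `coefficients` (intercept
#'   first), `fitted`, `residuals`, `r_squared`, `model_p`, `coef_p`,
#'   `coef_se`, `n` and `dof_model`.
#' @export
fit_lrm <- function(f, design) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  n <- length(f)
  if (nrow(X) != n)
    stop("design has ", nrow(X), " rows but response has length ", n)
  if (n < ncol(X) + 2L)
    stop("need at least ", ncol(X) + 2L,
         " observations for ", ncol(X), " predictors, got ", n)
  dat <- data.frame(.f = f, X, check.names = FALSE)
  fit <- stats::lm(.f ~ ., data = dat)
  sm <- summary(fit)
  co <- stats::coef(fit)
  co[is.na(co)] <- 0
  ct <- sm$coefficients  # rows only for non-aliased terms
  coef_p <- coef_se <- stats::setNames(rep(NA_real_, length(co)), names(co))
  coef_p[rownames(ct)] <- ct[, "Pr(>|t|)"]
  coef_se[rownames(ct)] <- ct[, "Std. Error"]
  fs <- sm$fstatistic
  model_p <- if (is.null(fs)) 1 else
    stats::pf(fs[["value"]], fs[["numdf"]], fs[["dendf"]], lower.tail = FALSE)
  structure(list(coefficients = co,
                 fitted = as.numeric(stats::fitted(fit)),
                 residuals = as.numeric(stats::resid(fit)),
                 r_squared = sm$r.squared,
                 model_p = as.numeric(model_p),
                 coef_p = coef_p, coef_se = coef_se,
                 n = n, dof_model = fit$rank - 1L),
            class = "lrm_fit")
}

#' @export
print.lrm_fit <- function(x, ...) {
  cat("<lrm_fit> n =", x$n, " model df =", x$dof_model,
      " R^2 =", signif(x$r_squared, 4),
      " p =", signif(x$model_p, 4), "\n")
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment `q_(i) = min_{j >= i} m p_(j) / j`, clipped at 1;
#' a feature is flagged when `q <= alpha`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param alpha Significance level (default 0.05).
#' @return List with `q` (adjusted p-values) and `significant` (logical).
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, significant = q <= alpha)
}

# fits every feature of `table` against its series' design; shared by the
# audit and by LRM normalization so residuals are computed once
fit_all_features <- function(table, designs) {
  stopifnot(inherits(table, "feature_table"))
  need <- setdiff(unique(table$meta$source_series), names(designs))
  if (length(need))
    stop("no design matrix supplied for series: ",
         paste(need, collapse = ", "))
  for (s in names(designs)) {
    d <- designs[[s]]
    if (!inherits(d, "design_matrix"))
      stop("designs[['", s, "']] is not a design_matrix")
    if (!identical(d$patient_ids, table$patient_ids))
      stop("patient order of design for series ", s,
           " does not match the feature table")
  }
  lapply(stats::setNames(seq_len(nrow(table$meta)), table$meta$feature_id),
         function(j) {
           s <- table$meta$source_series[j]
           fit_lrm(table$values[, j], designs[[s]])
         })
}

#' Audit features for association with MRI scanning parameters
#'
#' Fits the multilinear regression of every feature on its source series'
#' acquisition covariates and reports per-feature R^2, the overall-model
#' p-value, and the Benjamini-Hochberg q-value computed jointly across all
#' features of the table. R^2 and p-values are invariant to prior z-scoring
#' of the features.
#'
#' @param table A [feature_table()].
#' @param designs Named list mapping each source series present in the table
#'   to its [build_design_matrix()] result (patient order must match).
#' @param alpha FDR level (default 0.05).
#' @return A data frame of class `association_report` with columns
#'   `feature_id`, `source_series`, `group`, `r_squared`, `model_p`, `q`,
#'   `significant`; per-predictor p-values are kept in
#'   `attr(, "predictor_pvalues")` (named list) and `alpha` in
#'   `attr(, "alpha")`.
#' @export
association_audit <- function(table, designs, alpha = 0.05) {
  fits <- fit_all_features(table, designs)
  audit_from_fits(table, fits, alpha)
}

audit_from_fits <- function(table, fits, alpha) {
  p <- vapply(fits, `[[`, 0, "model_p")
  fdr <- bh_fdr(p, alpha)
  rep <- data.frame(
    feature_id = table$meta$feature_id,
    source_series = table$meta$source_series,
    group = table$meta$group,
    r_squared = vapply(fits, `[[`, 0, "r_squared"),
    model_p = p, q = fdr$q, significant = fdr$significant,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(rep, "predictor_pvalues") <- lapply(fits, `[[`, "coef_p")
  attr(rep, "alpha") <- alpha
  class(rep) <- c("association_report", "data.frame")
  rep
}

#' @export
print.association_report <- function(x, ...) {
  cat("<association_report> ", nrow(x), " features, ",
      sum(x$significant), " (", round(100 * mean(x$significant)),
      "%) FDR-significant at alpha = ", attr(x, "alpha"), "\n", sep = "")
  tab <- tapply(x$significant, x$source_series, function(v)
    sprintf("%d/%d", sum(v), length(v)))
  cat("  per series: ",
      paste(names(tab), unlist(tab), sep = " ", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Write an association report to CSV
#'
#' @param report An [association_audit()] result.
#' @param path Output CSV path.
#' @export
write_association_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Z-score normalize every feature column
#'
#' @param table A [feature_table()].
#' @return A `feature_table` tagged `ZSCORE`; metadata preserved.
#' @export
zscore_normalize_table <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  sds <- apply(table$values, 2, stats::sd)
  if (any(sds == 0))
    stop("zero variance feature(s): ",
         paste(table$meta$feature_id[sds == 0], collapse = ", "))
  vals <- scale(table$values)
  attr(vals, "scaled:center") <- attr(vals, "scaled:scale") <- NULL
  feature_table(vals, table$patient_ids, table$meta, "ZSCORE")
}

#' LRM-normalize a feature table
#'
#' The harmonization step: every feature is regressed on its source series'
#' acquisition covariates; for features whose model is FDR-significant at
#' level `alpha` the fitted values are subtracted (leaving the residual,
#' linearly unbiased from scanning protocol) before z-scoring, while
#' non-significant features are z-scored unchanged. A re-audit of the
#' returned table against the same designs flags no features.
#'
#' @inheritParams association_audit
#' @return List with `table` (a `feature_table` tagged `LRM`) and `report`
#'   (the [association_audit()] of the input, for provenance).
#' @export
lrm_normalize_table <- function(table, designs, alpha = 0.05) {
  fits <- fit_all_features(table, designs)
  report <- audit_from_fits(table, fits, alpha)
  vals <- table$values
  for (j in seq_len(ncol(vals))) {
    id <- table$meta$feature_id[j]
    v <- if (report$significant[j]) fits[[id]]$residuals else vals[, j]
    # an exactly protocol-determined feature leaves no residual to keep
    if (report$significant[j] &&
        stats::sd(v) <= 1e-10 * stats::sd(vals[, j]))
      stop("zero variance residual for feature '", id,
           "': feature is exactly determined by the scanning covariates")
    vals[, j] <- zscore(v, feature_id = id)
  }
  list(table = feature_table(vals, table$patient_ids, table$meta, "LRM"),
       report = report)
}
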