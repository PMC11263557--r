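test_that("z-scoring centers, scales, is idempotent and rejects constants", {
  expect_equal(zscore(c(2, 4, 6)), c(-1, 0, 1))
  v <- rnorm(50, 10, 3)
  z <- zscore(v)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(zscore(z), z)
  expect_error(zscore(c(5, 5, 5)), "zero variance")
  expect_error(zscore(c(5, 5, 5), feature_id = "T2_GLCM_Contrast"),
               "T2_GLCM_Contrast")
  expect_error(zscore(3), "at least 2")
})

test_that("exact linear data is fitted exactly", {
  x1 <- c(1, 2, 3, 4, 7)
  fit <- fit_lrm(3 + 2 * x1, cbind(x1 = x1))
  expect_equal(unname(fit$coefficients), c(3, 2), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$residuals, rep(0, 5), tolerance = 1e-10)
})

test_that("simple regression matches the hand-solved normal equations", {
  # f = [1,2,3,5], x = [1,2,3,4]: Sxx = 5, Sxy = 6.5 => slope 1.3,
  # intercept 2.75 - 1.3*2.5 = -0.5, R^2 = 8.45/8.75
  fit <- fit_lrm(c(1, 2, 3, 5), cbind(x1 = c(1, 2, 3, 4)))
  expect_equal(unname(fit$coefficients["x1"]), 1.3, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients["(Intercept)"]), -0.5,
               tolerance = 1e-12)
  expect_equal(fit$r_squared, 8.45 / 8.75, tolerance = 1e-12)
})

test_that("response orthogonal to centered predictors gives R^2 ~ 0", {
  X <- cbind(x1 = c(-1, 1, -1, 1, -1, 1))
  f <- c(1, 1, 2, 2, 3, 3)  # orthogonal to x1 after centering
  fit <- fit_lrm(f, X)
  expect_lt(fit$r_squared, 1e-20)
  expect_gt(fit$model_p, 0.99)
})

test_that("R^2 and model p are invariant to affine response transforms", {
  set.seed(11)
  X <- matrix(rnorm(40 * 3), 40, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  f <- 1 + X %*% c(0.5, 0, -0.3) + rnorm(40)
  base <- fit_lrm(as.numeric(f), X)
  for (tr in list(c(2, 0), c(-3, 7), c(0.01, -100))) {
    fit <- fit_lrm(as.numeric(tr[1] * f + tr[2]), X)
    expect_equal(fit$r_squared, base$r_squared, tolerance = 1e-10)
    expect_equal(fit$model_p, base$model_p, tolerance = 1e-10)
  }
})

test_that("residuals are orthogonal to every design column", {
  set.seed(12)
  n <- 60
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, letters[1:4]))
  f <- 2 + X %*% rnorm(4) + rnorm(n)
  fit <- fit_lrm(as.numeric(f), X)
  expect_lt(abs(sum(fit$residuals)), 1e-8 * n)
  for (j in 1:4)
    expect_lt(abs(sum(fit$residuals * X[, j])), 1e-8 * n)
})

test_that("rank-deficient designs are fitted with unchanged R^2", {
  set.seed(13)
  x <- rnorm(30)
  X <- cbind(a = x, b = 2 * x, c = rnorm(30))  # b aliased with a
  f <- 1 + x + rnorm(30)
  fit <- fit_lrm(f, X)
  ref <- fit_lrm(f, X[, c("a", "c")])
  expect_equal(fit$r_squared, ref$r_squared, tolerance = 1e-12)
  expect_equal(fit$coefficients[["b"]], 0)  # aliased column convention
  expect_error(fit_lrm(rnorm(4), matrix(rnorm(12), 4, 3)), "observations")
})

test_that("BH adjustment matches an independent step-up computation", {
  step_up <- function(p) {  # independent oracle: q_(i) = min_{j>=i} m p_(j)/j
    m <- length(p)
    o <- order(p)
    q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
    pmin(1, q_sorted)[order(o)]
  }
  expect_true(all(bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05)$significant))
  expect_false(any(bh_fdr(c(0.04, 0.5, 0.9), 0.05)$significant))
  r <- bh_fdr(0, 0.05)
  expect_true(r$significant)
  expect_equal(r$q, 0)
  set.seed(21)
  for (i in 1:5) {
    p <- runif(37)^2
    expect_equal(bh_fdr(p)$q, step_up(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH q-values are a monotone transform of the p-values", {
  set.seed(22)
  p <- runif(80)
  q <- bh_fdr(p)$q
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
})

test_that("the audit flags a constructed protocol-driven feature", {
  ids <- sprintf("P%d", 1:30)
  sp <- varied_scan_params(ids, "T2")
  sp$tr <- seq(4000, 6000, length.out = 30)
  sp <- scan_params(as.data.frame(sp))
  designs <- list(T2 = build_design_matrix(sp, ids, "T2"))
  meta <- build_feature_catalog("T2", include_shape = FALSE)[1:2, ]
  set.seed(30)
  vals <- cbind(2 * sp$tr + rnorm(30, 0, 0.01), rnorm(30))
  tab <- feature_table(vals, ids, meta)
  rep <- association_audit(tab, designs)
  expect_true(rep$significant[1])
  expect_gt(rep$r_squared[1], 0.999)
  expect_false(rep$significant[2])
  expect_true(all(rep$q >= rep$model_p))
})

test_that("audit R^2 values are identical before and after z-scoring", {
  coh <- small_cohort(seed = 5, n = 60, p_per_series = 10)
  a_raw <- association_audit(coh$table, coh$designs)
  a_z <- association_audit(zscore_normalize_table(coh$table), coh$designs)
  expect_equal(a_z$r_squared, a_raw$r_squared, tolerance = 1e-10)
  expect_equal(a_z$model_p, a_raw$model_p, tolerance = 1e-10)
})

test_that("table z-scoring normalizes every column and is idempotent", {
  tab <- tiny_table(n = 10, p = 3)
  zs <- zscore_normalize_table(tab)
  expect_equal(zs$normalization_tag, "ZSCORE")
  expect_true(all(abs(colMeans(zs$values)) < 1e-12))
  expect_true(all(abs(apply(zs$values, 2, sd) - 1) < 1e-12))
  expect_equal(zscore_normalize_table(zs)$values, zs$values)
  expect_equal(unname(zscore_normalize_table(tiny_table(3, 1,
    values = matrix(c(2, 4, 6))))$values[, 1]), c(-1, 0, 1))
  tab$values[, 2] <- 5
  tab <- feature_table(tab$values, tab$patient_ids, tab$meta)
  expect_error(zscore_normalize_table(tab), tab$meta$feature_id[2])
})

test_that("LRM normalization residualizes only FDR-significant features", {
  ids <- sprintf("P%d", 1:40)
  sp <- scan_params(as.data.frame(varied_scan_params(ids, "T2")))
  designs <- list(T2 = build_design_matrix(sp, ids, "T2"))
  meta <- build_feature_catalog("T2", include_shape = FALSE)[1:3, ]
  set.seed(31)
  # make the null column exactly orthogonal to the covariates so its model
  # R^2 is 0 by construction
  noise <- unname(resid(lm(rnorm(40) ~ designs$T2$X)))
  vals <- cbind(0.5 * sp$tr + rnorm(40, 0, 5),  # strongly biased
                noise,                          # protocol-independent
                rnorm(40))
  tab <- feature_table(vals, ids, meta)
  out <- lrm_normalize_table(tab, designs)
  expect_equal(out$table$normalization_tag, "LRM")
  expect_true(out$report$significant[1])
  expect_false(out$report$significant[2])
  # unassociated feature: LRM output equals the plain z-score output
  expect_equal(unname(out$table$values[, 2]), zscore(noise))
  # residualized feature no longer tracks TR
  expect_lt(abs(cor(out$table$values[, 1], sp$tr)), 0.2)
})

test_that("an exactly protocol-determined feature surfaces as zero variance", {
  ids <- sprintf("P%d", 1:25)
  sp <- scan_params(as.data.frame(varied_scan_params(ids, "T2")))
  designs <- list(T2 = build_design_matrix(sp, ids, "T2"))
  meta <- build_feature_catalog("T2", include_shape = FALSE)[1:2, ]
  vals <- cbind(3 + 2 * sp$tr, rnorm(25))  # exact linear in predictors
  tab <- feature_table(vals, ids, meta)
  expect_error(lrm_normalize_table(tab, designs), "zero variance")
})

test_that("re-auditing an LRM-normalized cohort flags nothing", {
  coh <- small_cohort(seed = 8, n = 70, p_per_series = 12)
  out <- lrm_normalize_table(coh$table, coh$designs)
  expect_gt(sum(out$report$significant), 0)  # biases were present
  re <- association_audit(out$table, coh$designs)
  expect_equal(sum(re$significant), 0)
})

test_that("misaligned designs and missing series are rejected", {
  coh <- small_cohort(seed = 9, n = 30, p_per_series = 5)
  expect_error(association_audit(coh$table, coh$designs["T2"]), "ADC")
  d2 <- coh$designs
  d2$T2$patient_ids <- rev(d2$T2$patient_ids)
  expect_error(association_audit(coh$table, d2), "patient order")
})
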