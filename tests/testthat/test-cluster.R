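make_blobs <- function(n = 40, d = 5, sep = 10, seed = 1) {
  set.seed(seed)
  lab <- rep(1:2, each = n / 2)
  list(x = matrix(rnorm(n * d), n, d) + sep * (lab - 1), labels = lab)
}

test_that("k-medoids recovers well-separated blobs exactly", {
  bl <- make_blobs()
  cr <- kmedoids(bl$x, 2)
  agree <- max(mean(cr$labels == bl$labels), mean(cr$labels == 3 - bl$labels))
  expect_equal(agree, 1)
  expect_length(cr$medoid_indices, 2)
  expect_true(all(cr$labels %in% 1:2))
})

test_that("k = 1 returns the point minimizing summed dissimilarity", {
  set.seed(2)
  x <- matrix(rnorm(24), 12, 2)
  cr <- kmedoids(x, 1)
  expect_true(all(cr$labels == 1))
  d2 <- as.matrix(dist(x))^2
  expect_equal(cr$medoid_indices, unname(which.min(rowSums(d2))))
})

test_that("duplicated rows land in the same cluster", {
  bl <- make_blobs(n = 20, seed = 3)
  x <- rbind(bl$x, bl$x[7, ], bl$x[15, ])
  cr <- kmedoids(x, 2)
  expect_equal(cr$labels[21], cr$labels[7])
  expect_equal(cr$labels[22], cr$labels[15])
})

test_that("the swap phase never worsens the build objective", {
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rnorm(30 * 4), 30, 4)
    cr <- kmedoids(x, 2)
    expect_lte(cr$objective[["swap"]], cr$objective[["build"]] + 1e-12)
  }
  expect_error(kmedoids(matrix(rnorm(10), 5, 2), 6), "exceeds")
})

test_that("cluster alignment handles identity, global flips and half-moves", {
  base <- structure(list(patient_ids = sprintf("P%d", 1:20),
                         labels = rep(1:2, each = 10), k = 2L),
                    class = "cluster_result")
  flip <- base; flip$labels <- 3L - base$labels
  cmp <- align_and_compare(base, base)
  expect_equal(cmp$change_fraction, 0)
  expect_setequal(unique(cmp$groups), c("G1", "G2"))
  cmp <- align_and_compare(base, flip)
  expect_equal(cmp$change_fraction, 0)  # label symmetry
  half <- base; half$labels[c(1:5, 11:15)] <- 3L - half$labels[c(1:5, 11:15)]
  cmp <- align_and_compare(base, half)
  expect_equal(cmp$change_fraction, 0.5)
  expect_equal(sum(cmp$groups == "G3"), 10)
  k3 <- base; k3$k <- 3L
  expect_error(align_and_compare(base, k3), "k = 2")
})

test_that("change fraction never exceeds 0.5 and ignores patient order", {
  set.seed(4)
  for (i in 1:10) {
    a <- structure(list(patient_ids = sprintf("P%d", 1:30),
                        labels = sample(1:2, 30, TRUE), k = 2L),
                   class = "cluster_result")
    b <- a; b$labels <- sample(1:2, 30, TRUE)
    cmp <- align_and_compare(a, b)
    expect_lte(cmp$change_fraction, 0.5)
    perm <- sample(30)
    ap <- a; ap$patient_ids <- a$patient_ids[perm]; ap$labels <- a$labels[perm]
    bp <- b; bp$patient_ids <- b$patient_ids[perm]; bp$labels <- b$labels[perm]
    expect_equal(align_and_compare(ap, bp)$change_fraction,
                 cmp$change_fraction)
  }
})

test_that("relabeling puts the larger cluster first", {
  cr <- structure(list(patient_ids = sprintf("P%d", 1:10),
                       labels = c(rep(1L, 3), rep(2L, 7)),
                       medoid_indices = c(1L, 4L), k = 2L),
                  class = "cluster_result")
  rl <- relabel_largest_first(cr)
  expect_equal(sum(rl$labels == 1), 7)
})

test_that("a perfectly separating 2x2 table gives the closed-form chi-square", {
  cl <- structure(list(patient_ids = sprintf("P%d", 1:40),
                       labels = rep(1:2, each = 20), k = 2L),
                  class = "cluster_result")
  params <- data.frame(pe = rep(c("ROW", "COLUMN"), each = 20))
  rep <- cluster_param_enrichment(cl, params)
  # 2x2 table [[20,0],[0,20]]: chi-square = n = 40 on 1 df
  expect_equal(rep$test, "chi_square")
  expect_equal(rep$p, pchisq(40, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_lt(rep$p, 1e-6)
  expect_true(rep$over_represented)
})

test_that("enrichment flags constructed signals but not permuted nulls", {
  set.seed(5)
  cl <- structure(list(patient_ids = sprintf("P%d", 1:100),
                       labels = rep(1:2, each = 50), k = 2L),
                  class = "cluster_result")
  params <- data.frame(
    signal = cl$labels + rnorm(100, 0, 0.01),
    null = sample(rnorm(100)),      # identically distributed in both clusters
    constant = rep(1, 100))
  expect_message(rep <- cluster_param_enrichment(cl, params), "constant")
  expect_equal(nrow(rep), 2)
  expect_true(rep$over_represented[rep$parameter == "signal"])
  expect_false(rep$over_represented[rep$parameter == "null"])
  expect_equal(rep$test[rep$parameter == "signal"], "kruskal_wallis")
  expect_true(all(rep$q >= rep$p))
})

test_that("feature shrinking on identical tables yields a zero curve", {
  coh <- small_cohort(seed = 6, n = 40, p_per_series = 10)
  zs <- zscore_normalize_table(coh$table)
  curve <- shrink_sensitivity(zs, zs, reps = 3, seed = 1)
  expect_s3_class(curve, "shrink_curve")
  expect_equal(nrow(curve), 19)  # 0% to 90% in 5% steps
  expect_equal(curve$removal_fraction, seq(0, 0.9, 0.05))
  expect_true(all(curve$mean_change == 0))
})

test_that("the shrink curve is deterministic given the seed", {
  coh <- small_cohort(seed = 7, n = 40, p_per_series = 10)
  zs <- zscore_normalize_table(coh$table)
  lrm <- lrm_normalize_table(coh$table, coh$designs)$table
  c1 <- shrink_sensitivity(zs, lrm, reps = 2, seed = 11)
  c2 <- shrink_sensitivity(zs, lrm, reps = 2, seed = 11)
  expect_identical(c1, c2)
  expect_true(all(c1$mean_change >= 0 & c1$mean_change <= 0.5))
  expect_error(shrink_sensitivity(zs, lrm, max_removal = 0.999, seed = 1),
               "fewer than 2")
})

test_that("cluster disagreement shrinks as injected bias vanishes", {
  change_at <- function(r2) {
    coh <- gen_cohort(synthetic_config(
      n_patients = 80, n_features_per_series = 15, bias_r2 = r2,
      bias_sparsity = if (r2 == 0) 0 else 0.5, seed = 17))
    zs <- zscore_normalize_table(coh$table)
    lrm <- lrm_normalize_table(coh$table, coh$designs)$table
    align_and_compare(kmedoids(zs, 2), kmedoids(lrm, 2))$change_fraction
  }
  ch <- vapply(c(0.6, 0.25, 0), change_at, 0)
  expect_true(all(diff(ch) <= 0))
  expect_equal(ch[3], 0)  # no bias: LRM collapses to plain z-scoring
})
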