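# k-medoids patient clustering, cluster alignment between normalizations,
# scanning-parameter enrichment, and the feature-shrinking stability curve.

#' k-medoids (PAM) clustering of patients
#'
#' Partitions patients around medoids (PAM build + swap, run to a local
#' optimum of the summed within-cluster dissimilarity). The default
#' dissimilarity is squared Euclidean distance on the normalized feature
#' matrix. The procedure is deterministic; `seed` is recorded for provenance
#' and governs any downstream sampling.
#'
#' @param values Numeric matrix (patients x features) or a `feature_table`.
#'   Shape features should be excluded upstream.
#' @param k Number of clusters, `1 <= k < n`.
#' @param seed Integer recorded on the result.
#' @param distance `"squared_euclidean"` (default) or `"euclidean"`.
#' @return An object of class `cluster_result`: list with `patient_ids`,
#'   `labels` (1..k), `medoid_indices`, `k`, `seed`, `distance`,
#'   `objective` (summed dissimilarity to medoids, build and swap phase).
#' @export
kmedoids <- function(values, k, seed = 0L,
                     distance = c("squared_euclidean", "euclidean")) {
  distance <- match.arg(distance)
  if (inherits(values, "feature_table")) {
    ids <- values$patient_ids
    values <- values$values
  } else {
    values <- as.matrix(values)
    ids <- rownames(values)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  }
  n <- nrow(values)
  if (k > n) stop("k = ", k, " exceeds the number of patients (", n, ")")
  if (k < 1) stop("k must be >= 1")
  if (!all(is.finite(values))) stop("feature matrix contains non-finite values")
  d <- stats::dist(values)
  if (distance == "squared_euclidean") d <- d^2
  if (k == n) {
    labels <- seq_len(n); med <- seq_len(n); obj <- c(build = 0, swap = 0)
  } else {
    pf <- cluster::pam(d, k, diss = TRUE, keep.diss = FALSE)
    labels <- as.integer(pf$clustering)
    med <- as.integer(pf$id.med)
    obj <- pf$objective
  }
  structure(list(patient_ids = ids, labels = labels, medoid_indices = med,
                 k = as.integer(k), seed = as.integer(seed),
                 distance = distance, objective = obj),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> k =", x$k, " sizes:",
      paste(tabulate(x$labels, x$k), collapse = "/"),
      " objective =", signif(x$objective[["swap"]], 5), "\n")
  invisible(x)
}

#' Renumber a 2-cluster result so cluster 1 is the larger cluster
#'
#' Convention used when comparing normalizations: cluster 1 is the larger
#' cluster of the reference (z-score) clustering, propagated to the other
#' clustering by alignment.
#'
#' @param result A [kmedoids()] result with `k = 2`.
#' @return The result, labels flipped if cluster 2 was larger.
#' @export
relabel_largest_first <- function(result) {
  stopifnot(inherits(result, "cluster_result"), result$k == 2L)
  sizes <- tabulate(result$labels, 2L)
  if (sizes[2] > sizes[1]) {
    result$labels <- 3L - result$labels
    result$medoid_indices <- rev(result$medoid_indices)
  }
  result
}

#' Align two 2-cluster solutions and classify patients into G1/G2/G3
#'
#' Cluster labels carry no intrinsic order, so the second labeling is flipped
#' when flipping increases agreement with the first. Patients consistently in
#' cluster 1 form G1, consistently in cluster 2 form G2, and patients that
#' change cluster between the two solutions form G3; the change fraction is
#' `|G3| / n` (at most 0.5 after alignment).
#'
#' @param a,b [kmedoids()] results over the same patients with `k = 2`; `a`
#'   is the reference whose numbering is kept.
#' @return An object of class `cluster_comparison`: list with
#'   `patient_ids`, `labels_a`, `aligned_labels_b`, `groups`
#'   (`"G1"/"G2"/"G3"` per patient) and `change_fraction`.
#' @export
align_and_compare <- function(a, b) {
  stopifnot(inherits(a, "cluster_result"), inherits(b, "cluster_result"))
  if (a$k != 2L || b$k != 2L)
    stop("cluster comparison is defined for k = 2 solutions")
  if (!identical(a$patient_ids, b$patient_ids))
    stop("the two clusterings cover different patients or orders")
  lb <- b$labels
  if (mean(a$labels == (3L - lb)) > mean(a$labels == lb)) lb <- 3L - lb
  changed <- a$labels != lb
  groups <- ifelse(changed, "G3", ifelse(a$labels == 1L, "G1", "G2"))
  structure(list(patient_ids = a$patient_ids, labels_a = a$labels,
                 aligned_labels_b = lb, groups = groups,
                 change_fraction = mean(changed)),
            class = "cluster_comparison")
}

#' @export
print.cluster_comparison <- function(x, ...) {
  n <- length(x$patient_ids)
  cat("<cluster_comparison> ", sum(x$groups == "G3"), "/", n, " (",
      round(100 * x$change_fraction), "%) patients changed cluster",
      " [G1 ", sum(x$groups == "G1"), ", G2 ", sum(x$groups == "G2"),
      ", G3 ", sum(x$groups == "G3"), "]\n", sep = "")
  invisible(x)
}

#' Test scanning parameters for uneven distribution across clusters
#'
#' Continuous parameters are compared between clusters with the
#' Kruskal-Wallis test; categorical parameters (character or factor columns)
#' with the chi-square test on the contingency table (no continuity
#' correction). P-values are FDR-adjusted across parameters; a parameter is
#' reported over-represented when `q <= alpha`. Parameters constant across
#' patients are skipped with a message.
#'
#' @param clusters A [kmedoids()] result.
#' @param params Per-patient parameter data frame (e.g.
#'   [scan_param_table()]); a `patient_id` column, if present, must match the
#'   clustering's patients and is not tested.
#' @param alpha FDR level (default 0.05).
#' @return Data frame of class `enrichment_report` with columns `parameter`,
#'   `test`, `p`, `q`, `over_represented`.
#' @export
cluster_param_enrichment <- function(clusters, params, alpha = 0.05) {
  stopifnot(inherits(clusters, "cluster_result"), is.data.frame(params))
  if ("patient_id" %in% names(params)) {
    if (!identical(as.character(params$patient_id), clusters$patient_ids))
      stop("parameter table patients do not match the clustering")
    params <- params[, names(params) != "patient_id", drop = FALSE]
  } else if (nrow(params) != length(clusters$patient_ids))
    stop("parameter table has ", nrow(params), " rows for ",
         length(clusters$patient_ids), " clustered patients")
  g <- factor(clusters$labels)
  rows <- lapply(names(params), function(nm) {
    v <- params[[nm]]
    if (length(unique(v[!is.na(v)])) < 2L) {
      message("cluster_param_enrichment: skipping constant parameter '",
              nm, "'")
      return(NULL)
    }
    if (is.numeric(v)) {
      p <- stats::kruskal.test(v, g)$p.value
      test <- "kruskal_wallis"
    } else {
      p <- stats::chisq.test(table(v, g), correct = FALSE)$p.value
      test <- "chi_square"
    }
    data.frame(parameter = nm, test = test, p = p, stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  if (is.null(rep) || nrow(rep) == 0L)
    stop("no testable (non-constant) parameters")
  fdr <- bh_fdr(rep$p, alpha)
  rep$q <- fdr$q
  rep$over_represented <- fdr$significant
  attr(rep, "alpha") <- alpha
  class(rep) <- c("enrichment_report", "data.frame")
  rep
}

#' Cluster-stability curve under random feature removal
#'
#' Measures how the disagreement between the clusterings of two
#' normalizations of the same cohort reacts to shrinking the feature set.
#' For each removal fraction (0%, 5%, ..., up to `max_removal`, stopping with
#' 10% of features remaining) a random feature subset is drawn `reps` times
#' — the same subset applied to both tables — both tables are re-clustered,
#' and the aligned change fraction is recorded.
#'
#' @param table_z,table_lrm [feature_table()]s over the same patients and
#'   feature ids (typically z-score- and LRM-normalized; shape features are
#'   dropped if present).
#' @param k Number of clusters (2).
#' @param reps Random subsets per removal fraction (default 50).
#' @param step Removal increment (default 0.05).
#' @param max_removal Largest removal fraction (default 0.90).
#' @param seed Integer seed making the curve reproducible.
#' @param shared_subsets Draw one subset per rep and apply it to both tables
#'   (default `TRUE`); `FALSE` resamples independently per table.
#' @return Data frame of class `shrink_curve` with columns
#'   `removal_fraction`, `mean_change`, `sd_change`, and attribute `reps`.
#' @export
shrink_sensitivity <- function(table_z, table_lrm, k = 2L, reps = 50L,
                               step = 0.05, max_removal = 0.90, seed = 0L,
                               shared_subsets = TRUE) {
  stopifnot(inherits(table_z, "feature_table"),
            inherits(table_lrm, "feature_table"))
  if (any(table_z$meta$group == "SHAPE")) table_z <- drop_shape_features(table_z)
  if (any(table_lrm$meta$group == "SHAPE"))
    table_lrm <- drop_shape_features(table_lrm)
  if (!identical(table_z$patient_ids, table_lrm$patient_ids))
    stop("tables cover different patients")
  if (!identical(table_z$meta$feature_id, table_lrm$meta$feature_id))
    stop("tables cover different features")
  p <- ncol(table_z$values)
  fracs <- seq(0, max_removal, by = step)
  if (p - round(max_removal * p) < 2L)
    stop("removal of ", max_removal * 100, "% would leave fewer than 2 of ",
         p, " features")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  res <- vapply(fracs, function(fr) {
    keep_n <- p - round(fr * p)
    ch <- vapply(seq_len(reps), function(r) {
      idx_z <- sample.int(p, keep_n)
      idx_l <- if (shared_subsets) idx_z else sample.int(p, keep_n)
      cz <- kmedoids(table_z$values[, idx_z, drop = FALSE], k, seed = seed)
      cl <- kmedoids(table_lrm$values[, idx_l, drop = FALSE], k, seed = seed)
      align_and_compare(cz, cl)$change_fraction
    }, 0)
    c(mean(ch), stats::sd(ch))
  }, c(0, 0))
  out <- data.frame(removal_fraction = fracs,
                    mean_change = res[1, ], sd_change = res[2, ])
  attr(out, "reps") <- as.integer(reps)
  class(out) <- c("shrink_curve", "data.frame")
  out
}
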