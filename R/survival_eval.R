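# Disease-specific survival evaluation: Kaplan-Meier curves, log-rank tests
# between cluster groups, and IPCW time-dependent AUC of radiomic survival
# models (random survival forest, LASSO Cox) over repeated 70/30 splits.

as_surv_df <- function(records) {
  stopifnot(inherits(records, "survival_records"))
  data.frame(time = records$time, event = as.integer(records$event))
}

#' Kaplan-Meier estimate of disease-specific survival
#'
#' Product-limit estimator; with censored-only data the curve stays at 1.
#'
#' @param records A [survival_records()] data frame.
#' @return Object of class `km_curve`: list with `times` (ordered unique
#'   follow-up times), `survival`, `at_risk`, `n_events`.
#' @export
km_curve <- function(records) {
  df <- as_surv_df(records)
  if (nrow(df) < 1L) stop("no survival records")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
  structure(list(times = fit$time, survival = fit$surv,
                 at_risk = fit$n.risk, n_events = fit$n.event),
            class = "km_curve")
}

#' Log-rank test between patient groups
#'
#' Standard observed-minus-expected chi-square statistic on
#' `(groups - 1)` degrees of freedom.
#'
#' @param records A [survival_records()] data frame.
#' @param group_labels Group membership per record (>= 2 non-empty groups).
#' @return Object of class `logrank_result`: list with `statistic`, `p`,
#'   `groups` (number of groups).
#' @export
logrank <- function(records, group_labels) {
  df <- as_surv_df(records)
  if (is.factor(group_labels) && any(table(group_labels) == 0L))
    stop("empty group(s): ",
         paste(levels(group_labels)[table(group_labels) == 0L],
               collapse = ", "))
  g <- factor(group_labels)
  if (length(g) != nrow(df))
    stop("group_labels length does not match the records")
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  structure(list(statistic = sd$chisq,
                 p = stats::pchisq(sd$chisq, nlevels(g) - 1L,
                                   lower.tail = FALSE),
                 groups = nlevels(g)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("<logrank> chi-square =", signif(x$statistic, 5), "on",
      x$groups - 1L, "df, p =", signif(x$p, 4), "\n")
  invisible(x)
}

#' Pairwise log-rank tests between all group pairs
#'
#' Used to compare disease-specific survival between the stable and
#' cluster-changing patient groups (G1/G2/G3).
#'
#' @inheritParams logrank
#' @return Data frame with columns `group1`, `group2`, `statistic`, `p`.
#' @export
logrank_pairwise <- function(records, group_labels) {
  g <- factor(group_labels)
  lv <- levels(g)
  if (length(lv) < 2L) stop("need at least 2 groups")
  pairs <- utils::combn(lv, 2L)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    sel <- g %in% pairs[, i]
    lr <- logrank(records[sel, , drop = FALSE], droplevels(g[sel]))
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               statistic = lr$statistic, p = lr$p,
               stringsAsFactors = FALSE)
  }))
}

#' IPCW cumulative/dynamic AUC at fixed horizons
#'
#' Uno-style estimator of the time-dependent AUC for right-censored data:
#' at horizon `t`, cases are subjects with an observed event by `t`,
#' controls are subjects still at risk beyond `t`; concordant
#' (case risk > control risk) pairs are counted with inverse probability of
#' censoring weights `1 / G(y_i)` for the cases, where `G` is the
#' Kaplan-Meier estimate of the censoring distribution (estimated on
#' training data). Risk ties count 0.5, so a constant risk score yields 0.5.
#'
#' @param time,event Follow-up time and event indicator of the evaluation
#'   set.
#' @param risk Risk score per evaluation subject (higher = earlier event).
#' @param horizons Evaluation times.
#' @param cens_records [survival_records()] used to estimate the censoring
#'   distribution (typically the training split); defaults to the
#'   evaluation data.
#' @return Numeric vector of AUC values (NA where no case/control pair
#'   exists at a horizon).
#' @export
tdauc_ipcw <- function(time, event, risk, horizons, cens_records = NULL) {
  stopifnot(length(time) == length(event), length(time) == length(risk))
  event <- as.integer(event)
  if (is.null(cens_records)) {
    cd <- data.frame(time = time, cens = 1L - event)
  } else {
    cd <- data.frame(time = cens_records$time,
                     cens = 1L - as.integer(cens_records$event))
  }
  cf <- survival::survfit(survival::Surv(time, cens) ~ 1, data = cd)
  G_at <- function(t) {
    # right-continuous KM of the censoring distribution, carried forward
    s <- c(1, cf$surv)[findInterval(t, cf$time) + 1L]
    pmax(s, 1e-12)
  }
  w <- 1 / G_at(time)
  vapply(horizons, function(t) {
    is_case <- time <= t & event == 1L
    is_ctrl <- time > t
    if (!any(is_case) || !any(is_ctrl)) return(NA_real_)
    rc <- risk[is_case]; wc <- w[is_case]; rk <- risk[is_ctrl]
    num <- sum(vapply(seq_along(rc), function(i)
      wc[i] * (sum(rc[i] > rk) + 0.5 * sum(rc[i] == rk)), 0))
    num / (sum(wc) * length(rk))
  }, 0)
}

#' Time-dependent AUC of survival prediction from radiomic features
#'
#' Evaluates how well a survival model trained on the feature table predicts
#' disease-specific survival, over repeated random 70/30 train/test splits
#' (stratified by event status). Per split, a random survival forest or an
#' L1-penalized (LASSO) Cox model is fitted on the training patients and the
#' IPCW cumulative/dynamic AUC of its risk score is computed on the test
#' patients over a grid of horizons; the censoring distribution for the
#' weights is estimated on the training split. The scalar summary
#' `mean_tdauc` averages first across splits at each horizon, then over the
#' horizon grid.
#'
#' @param features A [feature_table()] or numeric matrix (shape features are
#'   dropped if present).
#' @param records [survival_records()] covering the same patients (matched
#'   by `patient_id` when `features` is a `feature_table`); at least 10
#'   events are required.
#' @param model `"RSF"` (random survival forest) or `"LASSO_COX"`.
#' @param folds Number of repeated random splits (default 20).
#' @param train_fraction Training proportion per split (default 0.7).
#' @param seed Integer; all sampling and tree growing derive from it.
#' @param time_grid Evaluation horizons in months; default 15 equally spaced
#'   points between the 10th and 80th percentile of observed event times.
#' @param num_trees Trees for the RSF (default 100).
#' @return Object of class `tdauc_curve`: list with `time_grid`, `auc`
#'   (folds x horizons matrix), `mean_auc_t`, `sd_auc_t`, `mean_tdauc`,
#'   `model`, `folds`, `train_fraction`, `seed`.
#' @export
eval_tdauc <- function(features, records, model = c("RSF", "LASSO_COX"),
                       folds = 20L, train_fraction = 0.7, seed = 0L,
                       time_grid = NULL, num_trees = 100L) {
  model <- match.arg(model)
  if (inherits(features, "feature_table")) {
    if (any(features$meta$group == "SHAPE")) {
      message("eval_tdauc: dropping shape features")
      features <- drop_shape_features(features)
    }
    idx <- match(features$patient_ids, records$patient_id)
    if (anyNA(idx))
      stop("no survival record for patient(s): ",
           paste(features$patient_ids[is.na(idx)], collapse = ", "))
    records <- records[idx, , drop = FALSE]
    X <- features$values
  } else {
    X <- as.matrix(features)
    if (nrow(X) != nrow(records))
      stop("feature matrix and survival records differ in size")
  }
  n <- nrow(X)
  n_events <- sum(records$event)
  if (n_events < 10L)
    stop("only ", n_events, " events; at least 10 are needed for a stable ",
         "70/30 evaluation - consider pooling or longer follow-up")
  if (is.null(time_grid)) {
    et <- records$time[records$event]
    time_grid <- seq(stats::quantile(et, 0.1), stats::quantile(et, 0.8),
                     length.out = 15L)
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  ev_idx <- which(records$event)
  ce_idx <- which(!records$event)
  auc <- matrix(NA_real_, nrow = folds, ncol = length(time_grid))
  for (r in seq_len(folds)) {
    tr <- c(sample(ev_idx, round(train_fraction * length(ev_idx))),
            sample(ce_idx, round(train_fraction * length(ce_idx))))
    te <- setdiff(seq_len(n), tr)
    risk <- switch(model,
      RSF = {
        # matrix interface: feature ids may contain characters the formula
        # interface rejects (e.g. "VIBE+C_...")
        fit <- ranger::ranger(
          x = X[tr, , drop = FALSE],
          y = survival::Surv(records$time[tr], as.integer(records$event[tr])),
          num.trees = num_trees, seed = sample.int(.Machine$integer.max, 1))
        pr <- stats::predict(fit, data = X[te, , drop = FALSE])
        rowSums(pr$chf)
      },
      LASSO_COX = {
        if (ncol(X) < 2L)
          stop("LASSO Cox requires at least 2 feature columns")
        y <- survival::Surv(records$time[tr], as.integer(records$event[tr]))
        lam <- tryCatch({
          cv <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y, family = "cox",
                                  alpha = 1, nfolds = 5L,
                                  lambda.min.ratio = 0.01,
                                  type.measure = "C")
          cv$lambda.min
        }, error = function(e) {
          cv <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y, family = "cox",
                                  alpha = 1, nfolds = 5L,
                                  lambda.min.ratio = 0.01)
          cv$lambda.min
        })
        fit <- glmnet::glmnet(X[tr, , drop = FALSE], y, family = "cox",
                              alpha = 1, lambda.min.ratio = 0.01)
        as.numeric(stats::predict(fit, X[te, , drop = FALSE], s = lam,
                                  type = "link"))
      })
    auc[r, ] <- tdauc_ipcw(records$time[te], records$event[te], risk,
                           time_grid,
                           cens_records = records[tr, , drop = FALSE])
  }
  mean_t <- colMeans(auc, na.rm = TRUE)
  structure(list(time_grid = time_grid, auc = auc,
                 mean_auc_t = mean_t,
                 sd_auc_t = apply(auc, 2, stats::sd, na.rm = TRUE),
                 mean_tdauc = mean(mean_t, na.rm = TRUE),
                 model = model, folds = as.integer(folds),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "tdauc_curve")
}

#' @export
print.tdauc_curve <- function(x, ...) {
  cat("<tdauc_curve> ", x$model, ", ", x$folds, " x ",
      round(100 * x$train_fraction), "/", round(100 * (1 - x$train_fraction)),
      " splits: mean tdAUC = ", round(x$mean_tdauc, 3), "\n", sep = "")
  invisible(x)
}
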