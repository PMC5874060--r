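#' Fit trees of predictors for one or more horizons
#'
#' Full training pipeline on a development cohort: drop features with more
#' than \code{max_missing_fraction} missing entries, infer the feature
#' schema, encode to a numeric matrix, impute (mean/mode, fill values learned
#' on this cohort and frozen for scoring), then build one tree of predictors
#' per horizon. One tree per horizon because both the censoring discard rule
#' and the best (learner, cluster) structure are horizon-specific.
#'
#' @param table a \code{cohort_table} (the development set).
#' @param horizons numeric vector of horizons in days (defaults: 3 months,
#'   1, 3 and 10 years).
#' @param config a \code{build_config}.
#' @param max_missing_fraction missingness filter threshold (default 0.10).
#' @param schema_overrides optional named kind overrides for
#'   \code{\link{infer_schema}}.
#' @return a \code{tops_fit}: trees (named by horizon), schema, imputation
#'   fills, dropped-feature report and the encoded column set.
#' @export
tops_fit <- function(table, horizons = c(91, 365, 1095, 3650),
                     config = build_config(), max_missing_fraction = 0.10,
                     schema_overrides = NULL) {
  flt <- filter_features_by_missingness(table, max_missing_fraction)
  schema <- infer_schema(flt$table, schema_overrides)
  fm <- impute(encode_features(flt$table, schema))
  trees <- lapply(horizons, function(h) {
    task <- make_horizon_labels(flt$table, h)
    build_tops(fm, flt$table, task, config)
  })
  names(trees) <- as.character(horizons)
  structure(list(trees = trees, horizons = horizons, schema = schema,
                 fills = attr(fm, "fills"), dropped = flt$dropped,
                 columns = colnames(fm$values), config = config),
            class = "tops_fit")
}

#' @export
print.tops_fit <- function(x, ...) {
  cat(sprintf("tops_fit: %d horizon(s) [%s days], %d encoded features\n",
              length(x$trees), paste(x$horizons, collapse = ", "),
              length(x$columns)))
  for (tr in x$trees) print(tr)
  invisible(x)
}

# Encode + impute a (new) cohort with a fitted pipeline's frozen schema/fills
encode_with_fit <- function(fit, table) {
  keep <- intersect(fit$schema$feature, names(table$covariates))
  if (length(keep) < nrow(fit$schema))
    stop(sprintf("cohort lacks features: %s",
                 paste(setdiff(fit$schema$feature, keep), collapse = ", ")))
  impute(encode_features(table, fit$schema), fills = fit$fills)
}

#' Score a cohort with a fitted pipeline
#'
#' @param fit a \code{tops_fit}.
#' @param table a \code{cohort_table} with the training features.
#' @param horizons horizons to score (default: all fitted).
#' @return numeric matrix, one column per horizon, risks in [0, 1].
#' @export
tops_score <- function(fit, table, horizons = fit$horizons) {
  fm <- encode_with_fit(fit, table)
  out <- vapply(as.character(horizons), function(h) {
    if (is.null(fit$trees[[h]]))
      stop(sprintf("no tree fitted at horizon %s", h))
    predict_tops(fit$trees[[h]], fm)
  }, numeric(n_subjects(table)))
  out <- matrix(out, nrow = n_subjects(table),
                dimnames = list(NULL, as.character(horizons)))
  out
}

#' k-fold cross-validated performance report
#'
#' Randomly partitions the cohort into k folds (deterministic given
#' \code{seed}); for each fold, fits the full pipeline on the remaining
#' folds (including the internal train/validation sub-split used for
#' split selection) and evaluates on the held-out fold: AUC per horizon under
#' the censoring discard rule, Harrell's C-index per horizon over all
#' held-out subjects (no discard), and the mean C-index across horizons.
#'
#' @param table a \code{cohort_table}.
#' @param horizons horizons in days.
#' @param config a \code{build_config}.
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param max_missing_fraction,schema_overrides passed to
#'   \code{\link{tops_fit}}.
#' @return a \code{cv_report}: summary data.frame (metric, horizon, mean,
#'   sd) plus per-fold values and fold assignments.
#' @export
cross_validate <- function(table, horizons = c(91, 365, 1095, 3650),
                           config = build_config(), k = 5, seed = 1,
                           max_missing_fraction = 0.10,
                           schema_overrides = NULL) {
  n <- n_subjects(table)
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  per_fold <- vector("list", k)
  for (i in seq_len(k)) {
    train <- subset_cohort(table, fold != i)
    test <- subset_cohort(table, fold == i)
    if (n_subjects(test) < 2) stop(sprintf("fold %d too small", i))
    fit <- tryCatch(
      tops_fit(train, horizons, config, max_missing_fraction,
               schema_overrides),
      error = function(e) stop(sprintf("fold %d: %s", i, conditionMessage(e))))
    scores <- tops_score(fit, test)
    rows <- list()
    cis <- numeric(0)
    for (h in horizons) {
      hc <- as.character(h)
      task <- make_horizon_labels(test, h)
      a <- if (length(unique(task$label[task$included])) == 2)
        auc(scores[task$included, hc], task$label[task$included])
      else NA_real_
      ci <- concordance_index(scores[, hc], test$time, test$event)
      cis <- c(cis, ci)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = c("auc", "cindex"), horizon = h, value = c(a, ci))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "cindex_mean", horizon = NA_real_, value = mean(cis))
    per_fold[[i]] <- cbind(fold = i, do.call(rbind, rows))
  }
  all <- do.call(rbind, per_fold)
  agg <- stats::aggregate(value ~ metric + horizon, data = all,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)),
                          na.action = stats::na.pass)
  summary <- data.frame(metric = agg$metric, horizon = agg$horizon,
                        mean = agg$value[, "mean"], sd = agg$value[, "sd"])
  cm <- all[all$metric == "cindex_mean", "value"]
  summary <- rbind(summary,
                   data.frame(metric = "cindex_mean", horizon = NA_real_,
                              mean = mean(cm), sd = stats::sd(cm)))
  rownames(summary) <- NULL
  structure(list(summary = summary, per_fold = all, k = k, seed = seed,
                 horizons = horizons),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  s <- x$summary
  s$report <- sprintf("%.3f ± %.3f", s$mean, s$sd)
  print(s[, c("metric", "horizon", "report")], row.names = FALSE)
  invisible(x)
}

#' Era-restricted train/test evaluation
#'
#' Trains on subjects whose \code{listing_date} falls in
#' \code{train_range} and evaluates on those in \code{test_range}
#' (inclusive bounds): the design used to measure adaptation to changing
#' clinical practice. Errors when the cohort has no listing dates.
#'
#' @param table a \code{cohort_table} with a \code{listing_date}.
#' @param train_range,test_range length-2 vectors of inclusive bounds,
#'   comparable with the listing dates (e.g. numeric years).
#' @param horizons horizons in days.
#' @param config a \code{build_config}.
#' @return list: metrics data.frame (auc/cindex per horizon), train/test
#'   sizes, and the fitted pipeline.
#' @export
evaluate_era <- function(table, train_range, test_range,
                         horizons = c(91, 365, 1095), config = build_config()) {
  ld <- table$listing_date
  if (is.null(ld))
    stop("era evaluation requires a listing_date column")
  tr <- which(ld >= train_range[1] & ld <= train_range[2])
  te <- which(ld >= test_range[1] & ld <= test_range[2])
  if (length(intersect(tr, te)) > 0)
    stop("train and test eras overlap")
  train <- subset_cohort(table, tr); test <- subset_cohort(table, te)
  fit <- tops_fit(train, horizons, config)
  scores <- tops_score(fit, test)
  rows <- lapply(horizons, function(h) {
    task <- make_horizon_labels(test, h)
    a <- if (length(unique(task$label[task$included])) == 2)
      auc(scores[task$included, as.character(h)], task$label[task$included])
    else NA_real_
    ci <- concordance_index(scores[, as.character(h)], test$time, test$event)
    data.frame(metric = c("auc", "cindex"), horizon = h, value = c(a, ci))
  })
  list(metrics = do.call(rbind, rows), n_train = length(tr),
       n_test = length(te), fit = fit)
}
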