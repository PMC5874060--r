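#' Construct a cohort table
#'
#' A cohort table holds one row per subject: mixed-type covariates, a
#' follow-up time in days and an event indicator (1 = death observed at
#' \code{time}, 0 = right-censored at \code{time}).
#'
#' @param covariates data.frame of covariates (any mix of numeric, character
#'   or factor columns; \code{NA} or empty string marks a missing entry).
#' @param time numeric vector of non-negative follow-up times (days).
#' @param event integer/numeric vector of 0/1 event indicators.
#' @param subject_id optional vector of unique subject identifiers.
#' @param listing_date optional per-subject date (or numeric year) used only
#'   by era-restricted experiments; never treated as a covariate.
#' @return an object of class \code{cohort_table}.
#' @export
cohort_table <- function(covariates, time, event, subject_id = NULL,
                         listing_date = NULL) {
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  n <- nrow(covariates)
  if (n == 0L) stop("empty cohort")
  if (length(time) != n || length(event) != n)
    stop("time/event length must match number of subjects")
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (anyNA(time) || any(time < 0)) stop("followup_time must be >= 0")
  if (anyNA(event) || !all(event %in% c(0, 1))) stop("event must be 0 or 1")
  if (is.null(subject_id)) subject_id <- seq_len(n)
  if (anyDuplicated(subject_id)) stop("subject_ids must be unique")
  # character columns: empty string means missing
  for (j in seq_along(covariates)) {
    if (is.character(covariates[[j]])) {
      covariates[[j]][!is.na(covariates[[j]]) & covariates[[j]] == ""] <- NA
    } else if (is.factor(covariates[[j]])) {
      covariates[[j]] <- as.character(covariates[[j]])
    }
  }
  structure(list(subject_id = subject_id, covariates = covariates,
                 time = time, event = event, listing_date = listing_date),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d subjects, %d covariates, %d events (%.1f%% censored)\n",
              n_subjects(x), ncol(x$covariates), sum(x$event),
              100 * mean(x$event == 0)))
  invisible(x)
}

#' Number of subjects in a cohort table
#' @param table a \code{cohort_table}.
#' @export
n_subjects <- function(table) length(table$time)

#' Read a cohort from a delimited text file
#'
#' Expects a header with reserved columns \code{time} (days) and \code{event}
#' (0/1); an optional \code{subject_id} column and an optional
#' \code{listing_date} column (used only for era filtering); all remaining
#' columns are covariates. Empty strings and \code{NA} are missing.
#'
#' @param path CSV file path.
#' @param sep field separator (default comma).
#' @return a \code{cohort_table}.
#' @export
read_cohort <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  for (col in c("time", "event"))
    if (!col %in% names(df)) stop(sprintf("missing required column '%s'", col))
  id <- if ("subject_id" %in% names(df)) df$subject_id else NULL
  ld <- if ("listing_date" %in% names(df)) df$listing_date else NULL
  drop <- intersect(c("time", "event", "subject_id", "listing_date"), names(df))
  cov <- df[, setdiff(names(df), drop), drop = FALSE]
  cohort_table(cov, df$time, df$event, subject_id = id, listing_date = ld)
}

#' Write a cohort table to CSV
#' @param table a \code{cohort_table}.
#' @param path output file path.
#' @export
write_cohort <- function(table, path) {
  df <- cbind(data.frame(subject_id = table$subject_id),
              table$covariates,
              data.frame(time = table$time, event = table$event))
  if (!is.null(table$listing_date)) df$listing_date <- table$listing_date
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subset a cohort table by subject index
#' @param table a \code{cohort_table}.
#' @param idx integer or logical subject index.
#' @export
subset_cohort <- function(table, idx) {
  structure(list(subject_id = table$subject_id[idx],
                 covariates = table$covariates[idx, , drop = FALSE],
                 time = table$time[idx], event = table$event[idx],
                 listing_date = if (is.null(table$listing_date)) NULL
                                else table$listing_date[idx]),
            class = "cohort_table")
}

#' Infer a feature schema from a cohort
#'
#' Kinds are inferred as: at most 2 distinct non-missing values -> binary;
#' otherwise non-numeric -> categorical; otherwise continuous. Overrides take
#' precedence. Missing fractions are recorded per source feature.
#'
#' @param table a \code{cohort_table}.
#' @param overrides named character vector/list mapping feature name to kind
#'   (\code{"binary"}, \code{"categorical"} or \code{"continuous"}).
#' @return a \code{feature_schema}: data.frame with columns \code{feature},
#'   \code{kind}, \code{missing_fraction} and a \code{categories} attribute
#'   (named list of observed category sets).
#' @export
infer_schema <- function(table, overrides = NULL) {
  cov <- table$covariates
  n <- n_subjects(table)
  kinds <- character(ncol(cov)); miss <- numeric(ncol(cov))
  cats <- vector("list", ncol(cov)); names(cats) <- names(cov)
  for (j in seq_along(cov)) {
    v <- cov[[j]]
    miss[j] <- sum(is.na(v)) / n
    obs <- unique(v[!is.na(v)])
    kind <- if (length(obs) <= 2) "binary"
            else if (!is.numeric(v)) "categorical"
            else "continuous"
    ov <- overrides[[names(cov)[j]]]
    if (!is.null(ov)) {
      if (!ov %in% c("binary", "categorical", "continuous"))
        stop(sprintf("unknown kind '%s' for feature '%s'", ov, names(cov)[j]))
      kind <- ov
    }
    kinds[j] <- kind
    if (kind %in% c("binary", "categorical"))
      cats[[j]] <- sort(as.character(obs))
  }
  schema <- data.frame(feature = names(cov), kind = kinds,
                       missing_fraction = miss, stringsAsFactors = FALSE)
  attr(schema, "categories") <- cats
  class(schema) <- c("feature_schema", "data.frame")
  schema
}

#' Drop features exceeding a missingness threshold
#'
#' A feature is dropped when strictly more than \code{max_fraction} of its
#' entries are missing (a feature at exactly the threshold is retained).
#'
#' @param table a \code{cohort_table}.
#' @param max_fraction maximum tolerated missing fraction, in [0, 1]
#'   (default 0.10).
#' @return list with elements \code{table} (filtered cohort) and
#'   \code{dropped} (data.frame of dropped features with missing fractions,
#'   for logging).
#' @export
filter_features_by_missingness <- function(table, max_fraction = 0.10) {
  if (n_subjects(table) == 0L) stop("empty cohort")
  stopifnot(max_fraction >= 0, max_fraction <= 1)
  frac <- vapply(table$covariates, function(v) mean(is.na(v)), numeric(1))
  drop <- frac > max_fraction
  dropped <- data.frame(feature = names(table$covariates)[drop],
                        missing_fraction = unname(frac[drop]),
                        stringsAsFactors = FALSE)
  table$covariates <- table$covariates[, !drop, drop = FALSE]
  list(table = table, dropped = dropped)
}

#' Encode covariates as a numeric feature matrix
#'
#' Binary features map to a single 0/1 column (numeric 0/1 passes through
#' unchanged; a two-level categorical becomes an indicator of its second
#' sorted level). A categorical feature with k > 2 levels maps to k
#' one-vs-rest indicator columns. Continuous features pass through. Missing
#' entries remain \code{NA}; imputation is a separate step.
#'
#' @param table a \code{cohort_table}.
#' @param schema a \code{feature_schema} fitted on (a superset of) this data.
#' @return a \code{feature_matrix}: list with \code{values} (numeric matrix),
#'   \code{provenance} (data.frame mapping each encoded column to its source
#'   feature and category) and \code{binary} (logical per column).
#' @export
encode_features <- function(table, schema) {
  cats <- attr(schema, "categories")
  cols <- list(); prov <- list(); binflag <- logical(0)
  for (j in seq_len(nrow(schema))) {
    feat <- schema$feature[j]; kind <- schema$kind[j]
    v <- table$covariates[[feat]]
    if (is.null(v)) stop(sprintf("feature '%s' absent from table", feat))
    if (kind == "continuous") {
      cols[[feat]] <- as.numeric(v)
      prov[[length(prov) + 1L]] <- c(feat, feat, "identity")
      binflag <- c(binflag, FALSE)
    } else {
      lev <- cats[[feat]]
      obs <- unique(as.character(v[!is.na(v)]))
      unseen <- setdiff(obs, lev)
      if (length(unseen) > 0)
        stop(sprintf("unseen category for feature '%s': %s",
                     feat, paste(unseen, collapse = ", ")))
      if (kind == "binary") {
        if (is.numeric(v) && all(lev %in% c("0", "1"))) {
          cols[[feat]] <- as.numeric(v)
          prov[[length(prov) + 1L]] <- c(feat, feat, "identity")
        } else {
          pos <- lev[length(lev)]   # indicator of second sorted level
          nm <- paste0(feat, "=", pos)
          cols[[nm]] <- ifelse(is.na(v), NA_real_,
                               as.numeric(as.character(v) == pos))
          prov[[length(prov) + 1L]] <- c(nm, feat, pos)
        }
        binflag <- c(binflag, TRUE)
      } else {                       # categorical, one-vs-rest
        for (lv in lev) {
          nm <- paste0(feat, "=", lv)
          cols[[nm]] <- ifelse(is.na(v), NA_real_,
                               as.numeric(as.character(v) == lv))
          prov[[length(prov) + 1L]] <- c(nm, feat, lv)
          binflag <- c(binflag, TRUE)
        }
      }
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- NULL
  prov <- as.data.frame(do.call(rbind, prov), stringsAsFactors = FALSE)
  names(prov) <- c("column", "source", "category")
  structure(list(values = values, provenance = prov, binary = binflag),
            class = "feature_matrix")
}

#' Decode an encoded column back to its source value
#'
#' Inverts \code{encode_features} for one subject via the provenance map;
#' used to verify encoding round-trips.
#'
#' @param matrix a \code{feature_matrix}.
#' @param feature source feature name.
#' @param row subject row index.
#' @return the original categorical/continuous value (NA if unobserved).
#' @export
decode_feature <- function(matrix, feature, row) {
  prov <- matrix$provenance
  idx <- which(prov$source == feature)
  if (length(idx) == 0) stop(sprintf("unknown source feature '%s'", feature))
  if (length(idx) == 1 && prov$category[idx] == "identity")
    return(matrix$values[row, prov$column[idx]])
  vals <- matrix$values[row, prov$column[idx]]
  if (anyNA(vals)) return(NA_character_)
  if (length(idx) == 1)  # binary indicator of one level
    return(if (vals == 1) prov$category[idx] else
      stop("cannot decode 0 of a single binary indicator without the schema"))
  prov$category[idx][which(vals == 1)]
}

#' Impute missing entries by column mean/mode
#'
#' Continuous columns are filled with the column mean of observed values;
#' binary/indicator columns with the column mode (ties resolved to 0).
#' Fill values are computed on \code{fit_index} only (default: all rows) and
#' can be reused on held-out data by passing \code{fills}.
#'
#' @param matrix a \code{feature_matrix}, possibly with \code{NA} entries.
#' @param strategy imputation strategy; only \code{"mean_mode"} ships, the
#'   enum is the hook for richer imputers.
#' @param fit_index rows on which fill values are computed.
#' @param fills named numeric vector of precomputed fill values (overrides
#'   \code{fit_index}).
#' @return the completed \code{feature_matrix}, with the fill values attached
#'   as attribute \code{"fills"}.
#' @export
impute <- function(matrix, strategy = c("mean_mode"), fit_index = NULL,
                   fills = NULL) {
  strategy <- match.arg(strategy)
  v <- matrix$values
  if (is.null(fills)) {
    if (is.null(fit_index)) fit_index <- seq_len(nrow(v))
    fills <- numeric(ncol(v)); names(fills) <- colnames(v)
    for (j in seq_len(ncol(v))) {
      obs <- v[fit_index, j]; obs <- obs[!is.na(obs)]
      if (length(obs) == 0)
        stop(sprintf("column '%s' entirely missing on the fitting subset (should have been dropped by the missingness filter)",
                     colnames(v)[j]))
      fills[j] <- if (matrix$binary[j]) {
        if (sum(obs == 1) > sum(obs == 0)) 1 else 0
      } else mean(obs)
    }
  }
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (any(miss)) v[miss, j] <- fills[[colnames(v)[j]]]
  }
  matrix$values <- v
  attr(matrix, "fills") <- fills
  matrix
}

#' Binary mortality labels at a fixed horizon
#'
#' Casts survival prediction as binary classification of death within
#' \code{horizon} days. Subjects censored before the horizon carry no label
#' (their status at the horizon is unknown) and are excluded from binary
#' training and AUC evaluation; everyone else is labelled 1 if death was
#' observed within the horizon and 0 if follow-up reached the horizon alive.
#'
#' @param table a \code{cohort_table}.
#' @param horizon horizon in days (> 0).
#' @return a \code{horizon_task}: list with \code{horizon}, \code{label}
#'   (0/1, \code{NA} for excluded subjects) and \code{included} (logical).
#' @export
make_horizon_labels <- function(table, horizon) {
  stopifnot(horizon > 0)
  t <- table$time; e <- table$event
  included <- !(e == 0 & t < horizon)
  label <- ifelse(e == 1 & t <= horizon, 1L,
                  ifelse(t >= horizon, 0L, NA_integer_))
  label[!included] <- NA_integer_
  structure(list(horizon = horizon, label = as.integer(label),
                 included = included),
            class = "horizon_task")
}

#' Feature relevance scores within a cluster
#'
#' Absolute Pearson correlation between each encoded column and the binary
#' horizon label over the included subjects of \code{subset}. Constant
#' columns (or a constant label) score 0.
#'
#' @param matrix a completed \code{feature_matrix}.
#' @param task a \code{horizon_task}.
#' @param subset subject indices defining the cluster (default all).
#' @return named numeric vector of scores in [0, 1], one per encoded column.
#' @export
relevance_scores <- function(matrix, task, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(nrow(matrix$values))
  subset <- subset[task$included[subset]]
  if (length(subset) == 0) stop("no labeled subjects in cluster")
  y <- task$label[subset]
  x <- matrix$values[subset, , drop = FALSE]
  sdy <- stats::sd(y)
  sc <- apply(x, 2, function(col) {
    if (stats::sd(col) == 0 || is.na(sdy) || sdy == 0) return(0)
    abs(stats::cor(col, y))
  })
  sc[is.na(sc)] <- 0
  sc
}

#' Stratified development split
#'
#' Partitions the included subjects of a horizon task into disjoint training
#' and validation sets, stratified by label so both classes appear in each
#' part. Deterministic given \code{seed}.
#'
#' @param task a \code{horizon_task}.
#' @param validation_fraction fraction held out for validation (0 < f < 1).
#' @param seed integer seed.
#' @return list with integer index vectors \code{train} and \code{validation}.
#' @export
split_development <- function(task, validation_fraction = 0.2, seed = 1) {
  stopifnot(validation_fraction > 0, validation_fraction < 1)
  idx <- which(task$included)
  y <- task$label[idx]
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("fewer than 2 subjects per class")
  val <- with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cl) {
      pool <- idx[y == cl]
      k <- max(1L, round(validation_fraction * length(pool)))
      sort(sample(pool, k))
    }), use.names = FALSE)
  })
  val <- sort(val)
  list(train = setdiff(idx, val), validation = val)
}

# Evaluate an expression under a temporary RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
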