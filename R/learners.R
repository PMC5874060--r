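#' The base learner class
#'
#' The base class of elementary model families available at every tree node,
#' in canonical order (used for deterministic tie-breaking): Cox proportional
#' hazards, linear probability model, ridge-stabilized logistic regression.
#' @export
LEARNER_KINDS <- c("COX", "LINEAR", "LOGISTIC")

# Per-training-subset standardization: continuous columns to mean 0 / sd 1,
# binary columns untouched. Constant columns get scale 1 (coefficient 0).
standardizer <- function(x, binary) {
  center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  cont <- !binary
  if (any(cont)) {
    center[cont] <- colMeans(x[, cont, drop = FALSE])
    s <- apply(x[, cont, drop = FALSE], 2, stats::sd)
    s[is.na(s) | s == 0] <- 1
    scale[cont] <- s
  }
  list(center = center, scale = scale)
}

apply_standardizer <- function(x, std) {
  sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
}

# Ridge-penalized logistic regression by iteratively reweighted least squares.
# Small fixed L2 on the slopes (not the intercept) keeps the solve well-posed
# on small or near-separable clusters without materially biasing coefficients.
ridge_logistic <- function(x, y, lambda = 1e-4, max_iter = 50, tol = 1e-8) {
  d <- ncol(x)
  xi <- cbind(1, x)
  beta <- rep(0, d + 1L)
  pen <- diag(c(0, rep(lambda, d)), d + 1L)
  for (it in seq_len(max_iter)) {
    eta <- drop(xi %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    xtw <- t(xi * w)
    beta_new <- tryCatch(solve(xtw %*% xi + pen, xtw %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) stop("ridge logistic solve failed")
    beta_new <- drop(beta_new)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  beta
}

# Breslow estimate of the baseline cumulative hazard at `horizon`, given the
# linear predictors of the training subjects (eta = 0 at mean covariates).
breslow_cumhaz <- function(time, event, eta, horizon) {
  ord <- order(time)
  ts <- time[ord]; es <- event[ord]; rs <- exp(eta[ord])
  rev_cum <- rev(cumsum(rev(rs)))       # risk-set sum at each sorted position
  death_t <- ts[es == 1 & ts <= horizon]
  if (length(death_t) == 0) return(0)
  uniq <- unique(death_t)
  counts <- tabulate(match(death_t, uniq))
  at_risk <- rev_cum[match(uniq, ts)]   # first index with time >= u
  sum(counts / at_risk)
}

#' Fit a base learner on a cluster's training members
#'
#' All three learners score horizon mortality risk in [0, 1]. COX fits a
#' proportional-hazards model on (time, event) over every subject of the
#' subset (censored included) with a Breslow baseline survival estimate at
#' the task horizon; LINEAR fits a least-squares linear probability model and
#' LOGISTIC a lightly L2-regularized logistic model, both on the 0/1 horizon
#' labels of the included subjects only. Features are standardized on the
#' training subset inside the learner and the transform is reused at scoring
#' time.
#'
#' @param kind one of \code{LEARNER_KINDS}.
#' @param matrix a completed \code{feature_matrix}.
#' @param table the \code{cohort_table} (needed by COX for time/event).
#' @param task the \code{horizon_task}.
#' @param subset training subject indices.
#' @param node_id identifier of the cluster whose data trains the model.
#' @return a \code{fitted_model}: kind, column names, standardization,
#'   coefficients, intercept, baseline survival at the horizon (COX) and the
#'   training node id.
#' @export
fit_base_learner <- function(kind, matrix, table, task, subset,
                             node_id = "root") {
  kind <- match.arg(kind, LEARNER_KINDS)
  if (length(subset) == 0) stop("empty training subset")
  x_all <- matrix$values[subset, , drop = FALSE]

  if (kind == "COX") {
    std <- standardizer(x_all, matrix$binary)
    xs <- apply_standardizer(x_all, std)
    keep <- apply(xs, 2, function(c) stats::sd(c) > 0)
    beta <- rep(0, ncol(xs)); names(beta) <- colnames(xs)
    time <- table$time[subset]; event <- table$event[subset]
    if (any(keep) && sum(event) > 0) {
      fit <- tryCatch(
        survival::coxph.fit(xs[, keep, drop = FALSE],
                            survival::Surv(time, event),
                            strata = NULL, offset = NULL, init = NULL,
                            control = survival::coxph.control(iter.max = 50),
                            weights = NULL, method = "breslow",
                            rownames = NULL),
        error = function(e) NULL)
      if (is.null(fit))
        stop(sprintf("COX did not converge at node %s", node_id))
      co <- fit$coefficients
      co[is.na(co)] <- 0   # collinear columns (one-vs-rest redundancy)
      beta[keep] <- co
    }
    eta <- drop(xs %*% beta)
    h0 <- breslow_cumhaz(time, event, eta, task$horizon)
    model <- list(kind = kind, columns = colnames(matrix$values),
                  center = std$center, scale = std$scale,
                  coefficients = beta, intercept = 0,
                  baseline_survival = exp(-h0),
                  horizon = task$horizon, training_node_id = node_id)
    return(structure(model, class = "fitted_model"))
  }

  # binary learners: included subjects only, both classes required
  sub <- subset[task$included[subset]]
  y <- task$label[sub]
  if (length(unique(y)) < 2)
    stop(sprintf("degenerate labels for %s at node %s", kind, node_id))
  x <- matrix$values[sub, , drop = FALSE]
  std <- standardizer(x, matrix$binary)
  xs <- apply_standardizer(x, std)

  if (kind == "LINEAR") {
    fit <- stats::lm.fit(cbind(1, xs), y)
    co <- fit$coefficients
    co[is.na(co)] <- 0
    beta <- co[-1]; names(beta) <- colnames(xs)
    intercept <- co[1]
    bs <- NULL
  } else {                               # LOGISTIC
    co <- tryCatch(ridge_logistic(xs, y),
                   error = function(e)
                     stop(sprintf("LOGISTIC did not converge at node %s",
                                  node_id)))
    beta <- co[-1]; names(beta) <- colnames(xs)
    intercept <- co[1]
    bs <- NULL
  }
  structure(list(kind = kind, columns = colnames(matrix$values),
                 center = std$center, scale = std$scale,
                 coefficients = beta, intercept = intercept,
                 baseline_survival = bs,
                 horizon = task$horizon, training_node_id = node_id),
            class = "fitted_model")
}

#' Score horizon mortality risk with a fitted model
#'
#' COX: \code{1 - S0(horizon)^exp(eta)}; LINEAR: raw linear output clipped to
#' [0, 1]; LOGISTIC: sigmoid. Deterministic.
#'
#' @param model a \code{fitted_model}.
#' @param matrix a completed \code{feature_matrix} whose columns match the
#'   model's training columns.
#' @param subset subject indices to score (default all).
#' @return numeric risk scores in [0, 1].
#' @export
predict_risk <- function(model, matrix, subset = NULL) {
  cols <- colnames(matrix$values)
  if (!identical(cols, model$columns)) {
    missing <- setdiff(model$columns, cols)
    extra <- setdiff(cols, model$columns)
    stop(sprintf("column mismatch: missing [%s], extra [%s]",
                 paste(missing, collapse = ", "),
                 paste(extra, collapse = ", ")))
  }
  if (is.null(subset)) subset <- seq_len(nrow(matrix$values))
  x <- matrix$values[subset, , drop = FALSE]
  xs <- apply_standardizer(x, list(center = model$center,
                                   scale = model$scale))
  eta <- drop(xs %*% model$coefficients) + model$intercept
  switch(model$kind,
         COX = 1 - model$baseline_survival ^ exp(eta),
         LINEAR = pmin(1, pmax(0, eta)),
         LOGISTIC = 1 / (1 + exp(-eta)))
}

#' Serialize a fitted model to a plain list (JSON-ready)
#' @param model a \code{fitted_model}.
#' @export
model_to_list <- function(model) {
  list(kind = model$kind, columns = model$columns,
       center = model$center, scale = model$scale,
       coefficients = as.numeric(model$coefficients),
       intercept = model$intercept,
       baseline_survival = model$baseline_survival,
       horizon = model$horizon, training_node_id = model$training_node_id)
}

model_from_list <- function(l) {
  co <- as.numeric(l$coefficients); names(co) <- unlist(l$columns)
  structure(list(kind = l$kind, columns = unlist(l$columns),
                 center = as.numeric(l$center), scale = as.numeric(l$scale),
                 coefficients = co, intercept = l$intercept,
                 baseline_survival = if (is.null(l$baseline_survival)) NULL
                                     else as.numeric(l$baseline_survival),
                 horizon = l$horizon, training_node_id = l$training_node_id),
            class = "fitted_model")
}
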