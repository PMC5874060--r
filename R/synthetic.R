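#' Configuration for the synthetic heterogeneous-cohort generator
#'
#' Defines a survival cohort with planted threshold-defined clusters:
#' continuous covariates are standard normal, binary covariates
#' Bernoulli(0.5); an ordered list of (feature, threshold) rules partitions
#' subjects into up to 2^k clusters, each with its own coefficient vector and
#' baseline event rate; event times follow an exponential or Weibull
#' distribution with rate \code{lambda_k * exp(beta_k' x)}; censoring times
#' are uniform on (0, censoring_max), independent of covariates.
#'
#' @param n subject count.
#' @param d_continuous,d_binary covariate counts (features named
#'   \code{x1..}, \code{b1..}).
#' @param planted_splits list of \code{list(feature=, threshold=)} rules;
#'   cluster id = 1 + sum of bits \code{2^(j-1) * (x_fj >= tau_j)}.
#' @param beta numeric matrix, one row per cluster (2^k rows), one column per
#'   covariate; a single vector is recycled to all clusters.
#' @param lambda baseline event rate per cluster, events per year (> 0).
#' @param time_family \code{"exponential"} or \code{"weibull"}.
#' @param weibull_shape Weibull shape parameter (> 0; 1 = exponential).
#' @param censoring_max upper bound of the uniform censoring time, in days
#'   (\code{Inf} = no censoring).
#' @param seed integer seed.
#' @return a \code{synthetic_config} list.
#' @export
synthetic_config <- function(n, d_continuous = 4, d_binary = 2,
                             planted_splits = list(),
                             beta = NULL, lambda = 0.3,
                             time_family = c("exponential", "weibull"),
                             weibull_shape = 1, censoring_max = Inf,
                             seed = 1) {
  time_family <- match.arg(time_family)
  stopifnot(n >= 1, d_continuous >= 0, d_binary >= 0,
            all(lambda > 0), weibull_shape > 0, censoring_max > 0)
  d <- d_continuous + d_binary
  k <- 2L ^ length(planted_splits)
  if (is.null(beta)) beta <- rep(0, d)
  if (is.vector(beta)) beta <- matrix(beta, nrow = k, ncol = d, byrow = TRUE)
  stopifnot(nrow(beta) == k, ncol(beta) == d)
  lambda <- rep_len(lambda, k)
  feats <- c(if (d_continuous) paste0("x", seq_len(d_continuous)),
             if (d_binary) paste0("b", seq_len(d_binary)))
  colnames(beta) <- feats
  for (s in planted_splits)
    if (!s$feature %in% feats)
      stop(sprintf("planted split on unknown feature '%s'", s$feature))
  structure(list(n = as.integer(n), d_continuous = d_continuous,
                 d_binary = d_binary, features = feats,
                 planted_splits = planted_splits, beta = beta,
                 lambda = lambda, time_family = time_family,
                 weibull_shape = weibull_shape,
                 censoring_max = censoring_max, seed = as.integer(seed)),
            class = "synthetic_config")
}

DAYS_PER_YEAR <- 365

cluster_of <- function(config, x) {
  # x: matrix with named columns
  id <- rep(1L, nrow(x))
  for (j in seq_along(config$planted_splits)) {
    s <- config$planted_splits[[j]]
    id <- id + as.integer(x[, s$feature] >= s$threshold) *
      as.integer(2 ^ (j - 1))
  }
  id
}

#' Generate a synthetic cohort with oracle risks
#'
#' Deterministic given \code{config$seed}. Returns the cohort together with
#' the planted cluster id of every subject and a closed-form oracle risk
#' evaluator (the true probability of death within a horizon given the
#' subject's covariates).
#'
#' @param config a \code{synthetic_config}.
#' @return a \code{synthetic_cohort}: list with \code{cohort}
#'   (a \code{cohort_table}), \code{true_cluster}, \code{oracle_risk(horizon)}
#'   (vectorized over subjects) and \code{config}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  out <- with_seed(config$seed, {
    n <- config$n
    xc <- if (config$d_continuous)
      matrix(stats::rnorm(n * config$d_continuous), n) else NULL
    xb <- if (config$d_binary)
      matrix(stats::rbinom(n * config$d_binary, 1, 0.5), n) else NULL
    x <- cbind(xc, xb)
    colnames(x) <- config$features
    cl <- cluster_of(config, x)
    eta <- rowSums(x * config$beta[cl, , drop = FALSE])
    rate_day <- config$lambda[cl] * exp(eta) / DAYS_PER_YEAR
    e1 <- stats::rexp(n)
    t_event <- if (config$time_family == "exponential") e1 / rate_day
               else (e1 / rate_day) ^ (1 / config$weibull_shape)
    u <- if (is.finite(config$censoring_max))
      stats::runif(n, 0, config$censoring_max) else rep(Inf, n)
    list(x = x, cl = cl, rate_day = rate_day,
         time = pmin(t_event, u), event = as.numeric(t_event <= u))
  })
  cohort <- cohort_table(as.data.frame(out$x), out$time, out$event)
  shape <- config$weibull_shape
  expo <- config$time_family == "exponential"
  rate_day <- out$rate_day
  oracle <- function(horizon) {
    h <- if (expo) rate_day * horizon else rate_day * horizon ^ shape
    1 - exp(-h)
  }
  structure(list(cohort = cohort, true_cluster = out$cl,
                 oracle_risk = oracle, config = config),
            class = "synthetic_cohort")
}

#' Closed-form oracle risk for a feature vector
#'
#' True probability of death within \code{horizon} days for a subject with
#' covariates \code{x} under a synthetic configuration: exponential,
#' \code{1 - exp(-lambda_k exp(beta_k' x) h)}; Weibull analogue with the
#' configured shape (time measured in days, rates per year).
#'
#' @param config a \code{synthetic_config}.
#' @param x named numeric feature vector (or matrix of rows).
#' @param horizon horizon in days (>= 0).
#' @return probability (vector) in [0, 1).
#' @export
oracle_risk <- function(config, x, horizon) {
  stopifnot(horizon >= 0)
  if (is.null(dim(x)))
    x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  x <- x[, config$features, drop = FALSE]
  cl <- cluster_of(config, x)
  eta <- rowSums(x * config$beta[cl, , drop = FALSE])
  rate_day <- config$lambda[cl] * exp(eta) / DAYS_PER_YEAR
  h <- if (config$time_family == "exponential") rate_day * horizon
       else rate_day * horizon ^ config$weibull_shape
  1 - exp(-h)
}

#' Canonical synthetic study scenarios
#'
#' Three fixed cohort designs used throughout the package's tests and
#' examples. \code{"homogeneous"}: one population, a single coefficient
#' vector, nothing for the tree to discover. \code{"single_split"}: two
#' subpopulations at \code{x1 = 0} with opposing covariate effects and no
#' marginal effect of \code{x1} itself, so a global linear model is nearly
#' uninformative but the planted split is sharply identifiable.
#' \code{"four_cluster"}: two nested thresholds (\code{x1 = 0}, \code{x2 = 0})
#' giving four clusters with cluster-specific coefficient signs and baseline
#' rates, the heterogeneous-cohort setting where path-weighted node models
#' should beat any single global learner.
#'
#' @param name scenario name.
#' @param n subject count (defaults: 4000 / 4000 / 8000).
#' @param seed integer seed.
#' @return a \code{synthetic_config}.
#' @export
scenario_config <- function(name = c("homogeneous", "single_split",
                                     "four_cluster"),
                            n = NULL, seed = 1) {
  name <- match.arg(name)
  switch(name,
    homogeneous = synthetic_config(
      n = if (is.null(n)) 4000 else n, d_continuous = 4, d_binary = 2,
      beta = c(0.8, -0.5, 0.3, 0, 0.4, 0), lambda = 0.25,
      censoring_max = 10 * DAYS_PER_YEAR, seed = seed),
    single_split = synthetic_config(
      n = if (is.null(n)) 4000 else n, d_continuous = 4, d_binary = 2,
      planted_splits = list(list(feature = "x1", threshold = 0)),
      beta = rbind(c(0,  1.5, -1.0, 0,  0.8, 0),
                   c(0, -1.5,  1.0, 0, -0.8, 0)),
      lambda = c(0.4, 0.4),
      censoring_max = 10 * DAYS_PER_YEAR, seed = seed),
    four_cluster = synthetic_config(
      n = if (is.null(n)) 8000 else n, d_continuous = 4, d_binary = 2,
      planted_splits = list(list(feature = "x1", threshold = 0),
                            list(feature = "x2", threshold = 0)),
      beta = rbind(c(0, 0,  1.2,  1.0,  0.6, 0),
                   c(0, 0,  1.2, -1.0, -0.6, 0),
                   c(0, 0, -1.2,  1.0, -0.6, 0),
                   c(0, 0, -1.2, -1.0,  0.6, 0)),
      lambda = c(0.30, 0.45, 0.35, 0.55),
      censoring_max = 10 * DAYS_PER_YEAR, seed = seed))
}
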