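#' Area under the ROC curve (tie-aware Mann-Whitney)
#'
#' Fraction of (positive, negative) pairs where the positive scores higher,
#' with half credit for ties; computed from midranks. Death within the
#' horizon is the positive class throughout the package.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 labels.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Harrell's concordance index
#'
#' Over pairs (i, j) with \code{times[i] < times[j]} and \code{events[i] = 1},
#' the fraction where \code{scores[i] > scores[j]}, with half credit for
#' score ties; pairs with equal times and both events observed are comparable
#' with half credit. Censored subjects participate as the longer-time member
#' of comparable pairs; no subject is discarded.
#'
#' @param scores numeric risk scores (higher = shorter predicted survival).
#' @param times follow-up times.
#' @param events 0/1 event indicators.
#' @return concordance in [0, 1].
#' @export
concordance_index <- function(scores, times, events) {
  stopifnot(length(scores) == length(times), length(times) == length(events))
  comp <- 0; conc <- 0
  ev <- which(events == 1)
  for (i in ev) {
    later <- times > times[i]
    m <- sum(later)
    if (m > 0) {
      comp <- comp + m
      conc <- conc + sum(scores[i] > scores[later]) +
        0.5 * sum(scores[i] == scores[later])
    }
  }
  # equal event times, both events: each unordered pair once, half credit
  if (length(ev) > 1) {
    tev <- times[ev]
    dup <- table(tev)
    ties <- sum(choose(dup[dup > 1], 2))
    comp <- comp + ties
    conc <- conc + 0.5 * ties
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

#' Calibration curve and calibration RMSE (rho)
#'
#' Subjects are binned by score into equal-frequency bins (default deciles;
#' duplicated quantile boundaries are merged, never errored). Each bin
#' reports mean predicted risk, observed event rate, a normal-approximation
#' 95\% binomial confidence interval and its count; rho is the root mean
#' square distance between the (predicted, observed) points and the identity
#' line.
#'
#' @param scores numeric risk scores of included subjects.
#' @param labels 0/1 labels.
#' @param n_bins number of bins (>= 2, default 10).
#' @return a \code{calibration_report}: list with \code{bins} (data.frame)
#'   and \code{rho}.
#' @export
calibration <- function(scores, labels, n_bins = 10) {
  stopifnot(n_bins >= 2, length(scores) == length(labels))
  br <- unique(stats::quantile(scores, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  bin <- if (length(br) < 2) rep(1L, length(scores))
         else cut(scores, breaks = br, include.lowest = TRUE, labels = FALSE)
  ids <- sort(unique(bin))
  rows <- lapply(ids, function(b) {
    s <- scores[bin == b]; y <- labels[bin == b]
    p <- mean(y); n <- length(y)
    half <- 1.96 * sqrt(p * (1 - p) / n)
    data.frame(mean_predicted = mean(s), observed_rate = p,
               ci_lower = max(0, p - half), ci_upper = min(1, p + half),
               count = n)
  })
  bins <- do.call(rbind, rows)
  rho <- sqrt(mean((bins$mean_predicted - bins$observed_rate)^2))
  structure(list(bins = bins, rho = rho), class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("calibration: %d bins, rho = %.4f\n", nrow(x$bins), x$rho))
  print(x$bins, digits = 3)
  invisible(x)
}

#' Sensitivity at a fixed specificity
#'
#' Classifies a subject positive when score >= threshold; returns the
#' smallest threshold whose specificity reaches the target, the sensitivity
#' there, and the raw correct-positive / correct-negative counts (the counts
#' enable "correctly predicts N more patients" comparisons).
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 labels.
#' @param target_specificity required specificity, in (0, 1).
#' @return list: sensitivity, threshold, true_positives, true_negatives.
#' @export
sensitivity_at_specificity <- function(scores, labels, target_specificity) {
  stopifnot(target_specificity > 0, target_specificity < 1)
  pos <- labels == 1; neg <- labels == 0
  if (!any(pos) || !any(neg)) stop("single class")
  cand <- c(sort(unique(scores)), max(scores) + 1)
  spec <- vapply(cand, function(th) mean(scores[neg] < th), numeric(1))
  ok <- which(spec >= target_specificity)
  th <- cand[ok[1]]
  list(sensitivity = mean(scores[pos] >= th), threshold = th,
       true_positives = sum(pos & scores >= th),
       true_negatives = sum(neg & scores < th))
}

#' Specificity at a fixed sensitivity
#'
#' Mirror of \code{\link{sensitivity_at_specificity}}: returns the largest
#' threshold whose sensitivity reaches the target.
#'
#' @inheritParams sensitivity_at_specificity
#' @param target_sensitivity required sensitivity, in (0, 1).
#' @return list: specificity, threshold, true_positives, true_negatives.
#' @export
specificity_at_sensitivity <- function(scores, labels, target_sensitivity) {
  stopifnot(target_sensitivity > 0, target_sensitivity < 1)
  pos <- labels == 1; neg <- labels == 0
  if (!any(pos) || !any(neg)) stop("single class")
  cand <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(cand, function(th) mean(scores[pos] >= th), numeric(1))
  ok <- which(sens >= target_sensitivity)
  th <- cand[ok[1]]
  list(specificity = mean(scores[neg] < th), threshold = th,
       true_positives = sum(pos & scores >= th),
       true_negatives = sum(neg & scores < th))
}
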