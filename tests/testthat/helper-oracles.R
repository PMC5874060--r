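# Brute-force oracles, written independently of the package implementations:
# explicit pair enumeration and per-subject rule re-derivation.

auc_oracle <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0; win <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + 1
    if (scores[i] > scores[j]) win <- win + 1
    else if (scores[i] == scores[j]) win <- win + 0.5
  }
  win / tot
}

cindex_oracle <- function(scores, times, events) {
  n <- length(scores); comp <- 0; conc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (events[i] == 1 && times[i] < times[j]) {
      comp <- comp + 1
      if (scores[i] > scores[j]) conc <- conc + 1
      else if (scores[i] == scores[j]) conc <- conc + 0.5
    } else if (i < j && times[i] == times[j] &&
               events[i] == 1 && events[j] == 1) {
      comp <- comp + 1; conc <- conc + 0.5
    }
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

horizon_label_oracle <- function(time, event, horizon) {
  n <- length(time)
  included <- logical(n); label <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (event[i] == 0 && time[i] < horizon) {
      included[i] <- FALSE            # censored before horizon: unknown status
    } else {
      included[i] <- TRUE
      label[i] <- if (event[i] == 1 && time[i] <= horizon) 1L else 0L
    }
  }
  list(included = included, label = label)
}

# full ROC sweep used to cross-check the operating-point finders
roc_sweep_oracle <- function(scores, labels) {
  ths <- c(sort(unique(scores)), max(scores) + 1)
  data.frame(threshold = ths,
             sensitivity = vapply(ths, function(t)
               mean(scores[labels == 1] >= t), numeric(1)),
             specificity = vapply(ths, function(t)
               mean(scores[labels == 0] < t), numeric(1)))
}

# small mixed-type cohort used across preprocessing tests
toy_cohort <- function() {
  cohort_table(
    covariates = data.frame(
      age = c(50, 60, NA, 40, 55),
      sex = c("M", "F", "F", "M", "F"),
      blood = c("A", "B", "AB", "O", "A"),
      stringsAsFactors = FALSE),
    time = c(100, 400, 30, 800, 200),
    event = c(1, 0, 0, 1, 1))
}

# encoded development data for one synthetic scenario
prep_scenario <- function(name, n = NULL, seed = 1, horizon = 365) {
  sc <- generate_cohort(scenario_config(name, n = n, seed = seed))
  task <- make_horizon_labels(sc$cohort, horizon)
  fm <- impute(encode_features(sc$cohort, infer_schema(sc$cohort)))
  list(sc = sc, task = task, fm = fm, table = sc$cohort)
}
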