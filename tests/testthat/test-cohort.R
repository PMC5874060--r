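test_that("missingness filter drops strictly-above-threshold features only", {
  n <- 50
  cov <- data.frame(
    clean = rnorm(n),
    slightly = replace(rnorm(n), 1:5, NA),    # 10% exactly
    holey = replace(rnorm(n), 1:6, NA))       # 12%
  tab <- cohort_table(cov, time = rep(100, n), event = rep(1, n))
  res <- filter_features_by_missingness(tab, 0.10)
  expect_setequal(names(res$table$covariates), c("clean", "slightly"))
  expect_equal(res$dropped$feature, "holey")
  expect_equal(res$dropped$missing_fraction, 0.12)
  empty <- structure(list(subject_id = integer(0),
                          covariates = data.frame(x = numeric(0)),
                          time = numeric(0), event = numeric(0)),
                     class = "cohort_table")
  expect_error(filter_features_by_missingness(empty, 0.1), "empty cohort")
})

test_that("encoding: one-vs-rest indicators, identity pass-through, round-trip", {
  tab <- toy_cohort()
  schema <- infer_schema(tab)
  expect_equal(schema$kind[match(c("age", "sex", "blood"), schema$feature)],
               c("continuous", "binary", "categorical"))
  fm <- encode_features(tab, schema)
  blood_cols <- fm$provenance$column[fm$provenance$source == "blood"]
  expect_length(blood_cols, 4)           # A, AB, B, O -> is-X/not-X each
  sums <- rowSums(fm$values[, blood_cols])
  expect_true(all(sums == 1))            # observed rows sum to one
  expect_true(all(fm$values[, blood_cols] %in% c(0, 1)))
  # binary numeric 0/1 stays a single unchanged column
  tab2 <- cohort_table(data.frame(flag = c(0, 1, 1, 0)),
                       time = rep(10, 4), event = rep(1, 4))
  fm2 <- encode_features(tab2, infer_schema(tab2))
  expect_identical(colnames(fm2$values), "flag")
  expect_equal(fm2$values[, "flag"], c(0, 1, 1, 0))
  # provenance decodes back to the original category for observed entries
  for (i in seq_len(5))
    expect_equal(decode_feature(fm, "blood", i), tab$covariates$blood[i])
  # unseen category at transform time is a named error
  tab3 <- tab; tab3$covariates$blood[1] <- "Rh-null"
  expect_error(encode_features(tab3, schema), "blood.*Rh-null")
})

test_that("3-level categorical on 5 subjects gives 3 indicator columns summing to 1", {
  tab <- cohort_table(data.frame(grp = c("a", "b", "c", "a", "b")),
                      time = rep(10, 5), event = rep(1, 5))
  fm <- encode_features(tab, infer_schema(tab))
  expect_equal(ncol(fm$values), 3)
  # hand-enumerated indicator table
  expect_equal(unname(fm$values[, "grp=a"]), c(1, 0, 0, 1, 0))
  expect_equal(unname(fm$values[, "grp=b"]), c(0, 1, 0, 0, 1))
  expect_equal(unname(fm$values[, "grp=c"]), c(0, 0, 1, 0, 0))
  expect_equal(unname(rowSums(fm$values)), rep(1, 5))
})

test_that("mean/mode imputation fills from the fitting subset and is reusable", {
  m <- matrix(c(1, 2, NA, 3,
                0, 0, 1, NA), ncol = 2,
              dimnames = list(NULL, c("cont", "bin")))
  fm <- structure(list(values = m,
                       provenance = data.frame(column = c("cont", "bin"),
                                               source = c("cont", "bin"),
                                               category = "identity"),
                       binary = c(FALSE, TRUE)),
                  class = "feature_matrix")
  out <- impute(fm)
  expect_equal(unname(out$values[3, "cont"]), 2)      # mean of 1, 2, 3
  expect_equal(unname(out$values[4, "bin"]), 0)       # mode of 0, 0, 1
  expect_false(anyNA(out$values))
  # no missing entries -> identity
  expect_identical(impute(out)$values, out$values)
  # fills learned on a fitting subset are bit-identical on re-application
  fills <- attr(impute(fm, fit_index = 1:2), "fills")
  out2 <- impute(fm, fills = fills)
  expect_identical(attr(out2, "fills"), fills)
  expect_equal(unname(out2$values[3, "cont"]), 1.5)   # mean over rows 1-2 only
  # an all-missing column is an error, not a silent fill
  m2 <- m; m2[, 1] <- NA
  fm2 <- fm; fm2$values <- m2
  expect_error(impute(fm2), "missing")
})

test_that("horizon labels implement the censoring discard rule", {
  # months expressed in days; boundary cases from the stated rule
  tab <- cohort_table(data.frame(x = 1:3),
                      time = c(61, 30, 122), event = c(0, 1, 0))
  task <- make_horizon_labels(tab, 91)
  expect_equal(task$included, c(FALSE, TRUE, TRUE))
  expect_equal(task$label, c(NA_integer_, 1L, 0L))
  # brute-force re-derivation on random tables
  for (s in 1:20) {
    set.seed(s)
    n <- 40
    time <- round(runif(n, 0, 200)); event <- rbinom(n, 1, 0.5)
    tab <- cohort_table(data.frame(x = rnorm(n)), time, event)
    h <- sample(c(50, 91, 100), 1)
    task <- make_horizon_labels(tab, h)
    ora <- horizon_label_oracle(time, event, h)
    expect_identical(task$included, ora$included)
    expect_identical(task$label, ora$label)
    # invariants
    expect_true(all(task$label[task$included] %in% 0:1))
    expect_true(all(time[task$included & task$label == 1] <= h, na.rm = TRUE))
    expect_true(all(time[task$included & task$label == 0] >= h, na.rm = TRUE))
  }
})

test_that("relevance scores are absolute Pearson correlations", {
  n <- 100
  set.seed(2)
  y <- rep(0:1, each = n / 2)
  m <- cbind(same = y, noise = rnorm(n), const = 1)
  fm <- structure(list(values = m, binary = c(TRUE, FALSE, FALSE)),
                  class = "feature_matrix")
  tab <- cohort_table(data.frame(z = rnorm(n)), rep(200, n), rep(1, n))
  task <- make_horizon_labels(tab, 100)
  task$label <- as.integer(y)                 # attach the constructed labels
  sc <- relevance_scores(fm, task)
  expect_equal(unname(sc["same"]), 1)
  expect_equal(unname(sc["const"]), 0)
  # hand Pearson on the 4-point set
  m4 <- cbind(v = c(1, 2, 3, 4))
  fm4 <- structure(list(values = m4, binary = FALSE), class = "feature_matrix")
  task4 <- list(horizon = 1, label = c(0L, 0L, 1L, 1L),
                included = rep(TRUE, 4))
  expect_equal(unname(relevance_scores(fm4, task4)["v"]), 0.894, tolerance = 1e-3)
  # independence: large-n score near zero
  set.seed(3)
  mind <- cbind(u = rnorm(10000))
  fmi <- structure(list(values = mind, binary = FALSE), class = "feature_matrix")
  ti <- list(horizon = 1, label = rbinom(10000, 1, 0.5),
             included = rep(TRUE, 10000))
  expect_lt(unname(relevance_scores(fmi, ti)["u"]), 0.05)
  task$included[] <- FALSE
  expect_error(relevance_scores(fm, task), "no labeled subjects")
})

test_that("development split is stratified, disjoint and deterministic", {
  tab <- cohort_table(data.frame(x = rnorm(100)),
                      time = rep(200, 100), event = rep(1, 100))
  task <- make_horizon_labels(tab, 100)
  task$label <- as.integer(rep(0:1, each = 50))
  sp <- split_development(task, 0.2, seed = 7)
  expect_length(sp$validation, 20)
  expect_length(sp$train, 80)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), 1:100)
  # stratification: validation class proportions within one subject of 50/50
  expect_equal(sum(task$label[sp$validation] == 1), 10)
  # determinism
  sp2 <- split_development(task, 0.2, seed = 7)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_development(task, 0.2, seed = 8)))
  # degenerate class sizes
  task$label <- as.integer(c(1L, rep(0L, 99)))
  expect_error(split_development(task, 0.2, 1), "fewer than 2")
})
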