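test_that("path-weighted prediction is the hand-evaluated convex combination", {
  tree <- toy_tree(scores = c(0.2, 0.6), weights = c(0.3, 0.7))
  x <- c(x1 = -1, x2 = 0)
  expect_equal(predict_tops(tree, x), 0.3 * 0.2 + 0.7 * 0.6)  # 0.48
  # all path models emitting the same score s return s for any simplex weights
  tree2 <- toy_tree(scores = c(0.4, 0.4), weights = c(0.15, 0.85))
  expect_equal(predict_tops(tree2, x), 0.4)
  # column mismatch is an error
  expect_error(predict_tops(tree, c(x1 = 0, z = 1)), "column mismatch")
})

test_that("path weights: NNLS concentrates on the informative model, degeneracies go uniform", {
  set.seed(30)
  nv <- 40
  y <- rbinom(nv, 1, 0.5)
  m <- cbind(x1 = rep(-1, nv), x2 = rnorm(nv))
  fm <- structure(list(values = m, binary = c(FALSE, FALSE)),
                  class = "feature_matrix")
  task <- list(horizon = 365, label = as.integer(y), included = rep(TRUE, nv))
  tree <- toy_tree()
  tree$val_idx <- seq_len(nv)
  tree$nodes$n2$val_idx <- seq_len(nv)
  tree$nodes$n3$val_idx <- integer(0)
  # node n2's model reproduces the labels exactly; the root is noise
  noise_beta <- c(x1 = 0, x2 = 0.01)
  tree$nodes$n1$model$coefficients <- noise_beta
  tree$nodes$n1$model$intercept <- 0.5
  tree$nodes$n2$model <- structure(
    list(kind = "LOGISTIC", columns = c("x1", "x2"), center = c(0, 0),
         scale = c(1, 1), coefficients = c(x1 = 0, x2 = 0), intercept = 0,
         baseline_survival = NULL, horizon = 365, training_node_id = "n2"),
    class = "fitted_model")
  # make n2 emit the labels exactly via a LINEAR identity on a label column
  m2 <- cbind(x1 = as.numeric(y), x2 = rnorm(nv))
  fm2 <- structure(list(values = m2, binary = c(TRUE, FALSE)),
                   class = "feature_matrix")
  tree$nodes$n2$model <- const_model(0)
  tree$nodes$n2$model$coefficients <- c(x1 = 1, x2 = 0)
  tree <- fit_path_weights(tree, fm2, task, seq_len(nv))
  expect_gte(tree$path_weights$n2[["n2"]], 0.95)
  # every weight vector is a simplex point
  for (w in tree$path_weights) {
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-9)
  }
  # collinear path scores (identical models) fall back to uniform
  tree3 <- toy_tree(scores = c(0.5, 0.5))
  tree3$val_idx <- seq_len(nv)
  tree3$nodes$n2$val_idx <- seq_len(nv)
  tree3$nodes$n3$val_idx <- integer(0)
  tree3 <- fit_path_weights(tree3, fm2, task, seq_len(nv))
  expect_equal(unname(tree3$path_weights$n2), c(0.5, 0.5))
  # fewer than 10 validation members: uniform fallback
  tree4 <- toy_tree()
  tree4$val_idx <- 1:5
  tree4$nodes$n2$val_idx <- 1:5
  tree4$nodes$n3$val_idx <- integer(0)
  tree4 <- fit_path_weights(tree4, fm2, task, 1:5)
  expect_equal(unname(tree4$path_weights$n2), c(0.5, 0.5))
})

test_that("a planted threshold is discovered by the first accepted split", {
  fx <- prep_scenario("single_split", n = 4000, seed = 60)
  tree <- build_tops(fx$fm, fx$table, fx$task,
                     build_config(seed = 61, max_depth = 1))
  first <- tree$build_log[tree$build_log$stage == 1, ]
  expect_equal(first$feature, "x1")
  expect_lt(abs(first$threshold), 0.2)
  expect_gt(first$auc_node_after, first$auc_node_before + 1e-4)
  # exhaustive grid search at the root returns the same candidate
  sp <- split_development(fx$task, 0.2, 61)
  expect_equal(tree$nodes$n1$split$feature, "x1")
})

test_that("terminal regions partition the feature space", {
  fx <- prep_scenario("single_split", n = 2000, seed = 62)
  tree <- build_tops(fx$fm, fx$table, fx$task,
                     build_config(seed = 63, max_depth = 3))
  set.seed(64)
  q <- matrix(rnorm(1e4 * length(tree$columns)), ncol = length(tree$columns),
              dimnames = list(NULL, tree$columns))
  term <- topsurv:::route_to_terminal(tree, q)
  terminals <- names(Filter(function(n) is.null(n$child_ids), tree$nodes))
  expect_true(all(term %in% terminals))
  expect_true(all(nchar(term) > 0))
  # independent check: count terminal memberships by evaluating constraints
  sat <- sapply(terminals, function(tid) {
    con <- tree$nodes[[tid]]$constraints
    ok <- rep(TRUE, nrow(q))
    for (i in seq_len(nrow(con))) {
      v <- q[, con$feature[i]]
      ok <- ok & if (con$op[i] == "<") v < con$threshold[i]
                 else v >= con$threshold[i]
    }
    ok
  })
  expect_true(all(rowSums(sat) == 1))
  # predictions stay in [0, 1]
  p <- predict_tops(tree, q)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("build log AUC is non-decreasing and construction is monotone", {
  fx <- prep_scenario("four_cluster", n = 3000, seed = 65)
  tree <- build_tops(fx$fm, fx$table, fx$task,
                     build_config(seed = 66, max_depth = 4))
  expect_true(all(diff(tree$build_log$auc_tree) >= -1e-12))
  expect_true(all(tree$build_log$auc_node_after[-1] >
                    tree$build_log$auc_node_before[-1] + 1e-4 - 1e-12))
})

test_that("identical seed and config reproduce a bit-identical serialization", {
  fx <- prep_scenario("single_split", n = 1500, seed = 70)
  cfg <- build_config(seed = 71, max_depth = 2)
  t1 <- build_tops(fx$fm, fx$table, fx$task, cfg)
  t2 <- build_tops(fx$fm, fx$table, fx$task, cfg)
  expect_identical(as.character(tops_to_json(t1)),
                   as.character(tops_to_json(t2)))
  t3 <- build_tops(fx$fm, fx$table, fx$task, build_config(seed = 72,
                                                          max_depth = 2))
  expect_false(identical(as.character(tops_to_json(t1)),
                         as.character(tops_to_json(t3))))
})

test_that("JSON round-trip preserves predictions, description and DOT render", {
  fx <- prep_scenario("single_split", n = 1500, seed = 73)
  tree <- build_tops(fx$fm, fx$table, fx$task,
                     build_config(seed = 74, max_depth = 2))
  path <- file.path(tempdir(), "tree.json")
  tops_to_json(tree, path)
  tree2 <- tops_from_json(path)
  expect_equal(predict_tops(tree2, fx$fm), predict_tops(tree, fx$fm))
  d <- describe_tree(tree)
  expect_equal(nrow(d), length(tree$nodes))
  expect_true(all(!is.na(d$split_feature[!d$terminal])))
  expect_true(all(is.na(d$split_feature[d$terminal])))
  root_row <- d[is.na(d$parent_id), ]
  expect_equal(root_row$constraints, "(all)")
  dot <- tops_to_dot(tree)
  expect_match(dot, "digraph tops")
  expect_match(dot, "->")
  # training nodes weakly precede their nodes (lie on the root-path)
  for (n in tree$nodes) {
    path_ids <- topsurv:::root_path(tree, n$node_id)
    expect_true(n$training_node_id %in% path_ids)
  }
})

test_that("search declines degenerate nodes", {
  fx <- prep_scenario("single_split", n = 1500, seed = 75)
  tree <- build_tops(fx$fm, fx$table, fx$task,
                     build_config(seed = 76, max_depth = 1))
  # a node with too few training members for two admissible children
  tree$nodes$n1$train_idx <- tree$nodes$n1$train_idx[1:60]
  expect_null(search_best_split(tree, "n1", fx$fm, fx$table, fx$task,
                                build_config(seed = 76)))
  # single-label validation membership
  tree2 <- build_tops(fx$fm, fx$table, fx$task,
                      build_config(seed = 76, max_depth = 1))
  v <- tree2$nodes$n1$val_idx
  tree2$nodes$n1$val_idx <- v[fx$task$label[v] == 1]
  expect_null(search_best_split(tree2, "n1", fx$fm, fx$table, fx$task,
                                build_config(seed = 76)))
})

test_that("survival curves interpolate horizon risks with isotonic adjustment", {
  mk_tree <- function(h, risk) {
    tr <- toy_tree(scores = c(risk, risk), weights = c(0.5, 0.5))
    tr$horizon <- h
    for (nid in names(tr$nodes)) tr$nodes[[nid]]$model$horizon <- h
    tr
  }
  x <- c(x1 = 0.5, x2 = 0)
  # already monotone risks invert to survival unchanged
  trees <- Map(mk_tree, c(91, 365, 1095, 3650), c(0.1, 0.3, 0.5, 0.7))
  sc <- survival_curve(trees, x)
  expect_equal(sc$survival, c(1, 0.9, 0.7, 0.5, 0.3))
  expect_equal(sc$fn(0), 1)
  # linear midpoint between horizons with survivals 0.9 and 0.7
  expect_equal(sc$fn((91 + 365) / 2), 0.8)
  # pool-adjacent-violators: risks (0.3, 0.2) pooled to (0.25, 0.25)
  trees2 <- Map(mk_tree, c(365, 1095), c(0.3, 0.2))
  sc2 <- survival_curve(trees2, x)
  expect_equal(sc2$survival, c(1, 0.75, 0.75))
  expect_error(survival_curve(trees2[1], x), ">= 2 horizons")
})
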