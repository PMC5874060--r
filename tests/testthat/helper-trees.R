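# Hand-constructed one- and two-node trees for the closed-form contracts.

const_model <- function(score, columns = c("x1", "x2")) {
  structure(list(kind = "LINEAR", columns = columns,
                 center = rep(0, length(columns)),
                 scale = rep(1, length(columns)),
                 coefficients = setNames(rep(0, length(columns)), columns),
                 intercept = score, baseline_survival = NULL,
                 horizon = 365, training_node_id = "n1"),
            class = "fitted_model")
}

toy_tree <- function(scores = c(0.2, 0.6), weights = c(0.3, 0.7)) {
  nodes <- list(
    n1 = list(node_id = "n1", parent_id = NULL, depth = 0L,
              constraints = NULL,
              split = list(feature = "x1", threshold = 0),
              child_ids = c("n2", "n3"), n_train = 100, n_val = 20,
              model = const_model(scores[1]), training_node_id = "n1",
              val_auc = NA_real_, top_features = c("x1")),
    n2 = list(node_id = "n2", parent_id = "n1", depth = 1L,
              constraints = data.frame(feature = "x1", op = "<", threshold = 0),
              split = NULL, child_ids = NULL, n_train = 50, n_val = 10,
              model = const_model(scores[2]), training_node_id = "n2",
              val_auc = NA_real_, top_features = c("x2")),
    n3 = list(node_id = "n3", parent_id = "n1", depth = 1L,
              constraints = data.frame(feature = "x1", op = ">=", threshold = 0),
              split = NULL, child_ids = NULL, n_train = 50, n_val = 10,
              model = const_model(scores[2]), training_node_id = "n1",
              val_auc = NA_real_, top_features = c("x2")))
  structure(list(nodes = nodes, root_id = "n1", horizon = 365,
                 columns = c("x1", "x2"),
                 config = build_config(),
                 path_weights = list(n2 = setNames(weights, c("n1", "n2")),
                                     n3 = setNames(weights, c("n1", "n3"))),
                 build_log = data.frame(stage = 0)),
            class = "tops_tree")
}
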