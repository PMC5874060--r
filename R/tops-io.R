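constraint_string <- function(con) {
  if (is.null(con) || nrow(con) == 0) return("(all)")
  paste(sprintf("%s %s %.6g", con$feature, con$op, con$threshold),
        collapse = " & ")
}

#' Structured, human-readable tree summary
#'
#' One record per node: the conjunction of half-space constraints defining
#' its cluster, member counts, learner kind, training node, the three most
#' relevant features within the cluster, and the split rule for internal
#' nodes.
#'
#' @param tree a built \code{tops_tree}.
#' @return data.frame, one row per node (class \code{tops_description}).
#' @export
describe_tree <- function(tree) {
  rows <- lapply(tree$nodes, function(n) data.frame(
    node_id = n$node_id,
    parent_id = if (is.null(n$parent_id)) NA_character_ else n$parent_id,
    depth = n$depth,
    terminal = is.null(n$child_ids),
    constraints = constraint_string(n$constraints),
    n_train = n$n_train, n_val = n$n_val,
    learner = n$model$kind,
    training_node = n$training_node_id,
    split_feature = if (is.null(n$split)) NA_character_ else n$split$feature,
    split_threshold = if (is.null(n$split)) NA_real_ else n$split$threshold,
    top_features = paste(n$top_features, collapse = ", "),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("tops_description", "data.frame")
  out
}

#' Serialize a tree of predictors to JSON
#'
#' The JSON artifact is self-contained: reloading it with
#' \code{\link{tops_from_json}} reproduces predictions exactly.
#'
#' @param tree a built \code{tops_tree}.
#' @param path optional output file.
#' @return the JSON string, invisibly when \code{path} is given.
#' @export
tops_to_json <- function(tree, path = NULL) {
  nodes <- lapply(tree$nodes, function(n) list(
    node_id = n$node_id, parent_id = n$parent_id, depth = n$depth,
    constraints = n$constraints, split = n$split, child_ids = n$child_ids,
    n_train = n$n_train, n_val = n$n_val, val_auc = n$val_auc,
    training_node_id = n$training_node_id, top_features = n$top_features,
    model = model_to_list(n$model)))
  obj <- list(format = "tops_tree", package_version = "0.1.0",
              horizon = tree$horizon, columns = tree$columns,
              root_id = tree$root_id, config = tree$config,
              nodes = nodes,
              path_weights = lapply(tree$path_weights, function(w)
                list(nodes = names(w), weights = as.numeric(w))),
              build_log = tree$build_log)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Reload a serialized tree of predictors
#' @param path JSON file written by \code{\link{tops_to_json}} (or a JSON
#'   string).
#' @return a \code{tops_tree} usable for prediction and description.
#' @export
tops_from_json <- function(path) {
  l <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(l$format) || l$format != "tops_tree")
    stop("not a tops_tree JSON artifact")
  cols <- unlist(l$columns)
  nodes <- lapply(l$nodes, function(n) {
    con <- if (is.null(n$constraints)) NULL else
      do.call(rbind, lapply(n$constraints, function(r)
        data.frame(feature = r$feature, op = r$op, threshold = r$threshold,
                   stringsAsFactors = FALSE)))
    list(node_id = n$node_id, parent_id = n$parent_id, depth = n$depth,
         constraints = con,
         split = if (is.null(n$split)) NULL else
           list(feature = n$split$feature, threshold = n$split$threshold),
         child_ids = if (is.null(n$child_ids)) NULL else unlist(n$child_ids),
         n_train = n$n_train, n_val = n$n_val, val_auc = n$val_auc,
         training_node_id = n$training_node_id,
         top_features = unlist(n$top_features),
         model = model_from_list(n$model))
  })
  names(nodes) <- vapply(nodes, `[[`, "", "node_id")
  pw <- lapply(l$path_weights, function(w)
    stats::setNames(as.numeric(unlist(w$weights)), unlist(w$nodes)))
  bl_cols <- c("stage", "node", "feature", "threshold", "learner_left",
               "learner_right", "train_node_left", "train_node_right",
               "auc_node_before", "auc_node_after", "auc_tree")
  bl <- if (is.null(l$build_log)) NULL else
    do.call(rbind, lapply(l$build_log, function(r) {
      vals <- lapply(bl_cols, function(cn)
        if (is.null(r[[cn]])) NA else r[[cn]])   # NA fields omitted in JSON
      names(vals) <- bl_cols
      as.data.frame(vals, stringsAsFactors = FALSE)
    }))
  structure(list(nodes = nodes, root_id = l$root_id, horizon = l$horizon,
                 columns = cols, config = l$config, path_weights = pw,
                 build_log = bl),
            class = "tops_tree")
}

#' Render a tree of predictors as GraphViz DOT
#' @param tree a built \code{tops_tree}.
#' @param path optional output file.
#' @return the DOT string, invisibly when \code{path} is given.
#' @export
tops_to_dot <- function(tree, path = NULL) {
  lines <- c("digraph tops {", "  node [shape=box, fontname=\"Helvetica\"];")
  for (n in tree$nodes) {
    lab <- sprintf("%s\\n%s\\nlearner %s (trained on %s)\\nn=%d\\ntop: %s",
                   n$node_id, constraint_string(n$constraints), n$model$kind,
                   n$training_node_id, n$n_train,
                   paste(n$top_features, collapse = ", "))
    style <- if (is.null(n$child_ids)) ", style=filled, fillcolor=gray90" else ""
    lines <- c(lines, sprintf("  %s [label=\"%s\"%s];", n$node_id, lab, style))
    if (!is.null(n$split)) {
      lines <- c(lines,
        sprintf("  %s -> %s [label=\"%s < %.4g\"];",
                n$node_id, n$child_ids[1], n$split$feature, n$split$threshold),
        sprintf("  %s -> %s [label=\"%s >= %.4g\"];",
                n$node_id, n$child_ids[2], n$split$feature, n$split$threshold))
    }
  }
  lines <- c(lines, "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(path)) { writeLines(dot, path); return(invisible(dot)) }
  dot
}
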