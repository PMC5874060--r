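#' Configuration for tree-of-predictors construction
#'
#' @param learner_set subset of \code{LEARNER_KINDS} available at every node.
#' @param validation_fraction fraction of the development set held out for
#'   validation-driven split selection and path-weight fitting.
#' @param quantile_count number of quantile bins per feature used to form
#'   candidate thresholds (deciles by default; interior quantiles only,
#'   de-duplicated per node).
#' @param min_child_training_size minimum training members per child.
#' @param min_child_validation_per_class minimum validation members of each
#'   class per child.
#' @param improvement_epsilon minimum validation-AUC gain over the incumbent
#'   node model for a split to be accepted.
#' @param max_depth safety cap on tree depth.
#' @param seed integer seed controlling the development split.
#' @return a \code{build_config} list.
#' @export
build_config <- function(learner_set = LEARNER_KINDS,
                         validation_fraction = 0.2,
                         quantile_count = 10,
                         min_child_training_size = 50,
                         min_child_validation_per_class = 5,
                         improvement_epsilon = 1e-4,
                         max_depth = 10,
                         seed = 1) {
  stopifnot(all(learner_set %in% LEARNER_KINDS),
            validation_fraction > 0, validation_fraction < 1,
            quantile_count >= 2, min_child_training_size >= 1,
            min_child_validation_per_class >= 1,
            improvement_epsilon >= 0, max_depth >= 1)
  list(learner_set = LEARNER_KINDS[LEARNER_KINDS %in% learner_set],
       validation_fraction = validation_fraction,
       quantile_count = as.integer(quantile_count),
       min_child_training_size = as.integer(min_child_training_size),
       min_child_validation_per_class = as.integer(min_child_validation_per_class),
       improvement_epsilon = improvement_epsilon,
       max_depth = as.integer(max_depth),
       seed = as.integer(seed))
}

# Fit (and memoize) a learner on a node's own training members. The cache is
# an environment attached to the tree, so memoization survives list copies.
node_model <- function(tree, node_id, kind, matrix, table, task) {
  key <- paste(node_id, kind, sep = ":")
  if (!is.null(tree$cache) && !is.null(tree$cache[[key]])) {
    m <- tree$cache[[key]]
    return(if (is.character(m)) NULL else m)   # "failed" sentinel
  }
  m <- tryCatch(
    fit_base_learner(kind, matrix, table, task,
                     tree$nodes[[node_id]]$train_idx, node_id = node_id),
    error = function(e) NULL)
  if (!is.null(tree$cache))
    tree$cache[[key]] <- if (is.null(m)) "failed" else m
  m
}

root_path <- function(tree, node_id) {
  path <- node_id
  while (!is.null(tree$nodes[[node_id]]$parent_id)) {
    node_id <- tree$nodes[[node_id]]$parent_id
    path <- c(node_id, path)
  }
  path
}

#' Search the best admissible split of a terminal node
#'
#' Enumerates the joint candidate grid: every encoded feature, every interior
#' quantile threshold of that feature over the node's training members, every
#' pair of learners from the configured base class, and every pair of
#' training nodes drawn from the node's root-path plus the prospective child
#' itself. Each candidate trains the two side models, scores the node's
#' validation members with the combined scorer and measures its AUC. Returns
#' the argmax candidate if it beats the incumbent node model's validation AUC
#' by more than \code{improvement_epsilon}, otherwise \code{NULL}. Ties break
#' deterministically: lower feature column index, then smaller threshold,
#' then learner order COX < LINEAR < LOGISTIC (left side then right), then
#' shallower training node (prospective child last).
#'
#' @param tree a \code{tops_tree} under construction.
#' @param node_id terminal node to split.
#' @param matrix,table,task the development data.
#' @param config a \code{build_config}.
#' @return a split candidate (list) or \code{NULL}.
#' @export
search_best_split <- function(tree, node_id, matrix, table, task, config) {
  node <- tree$nodes[[node_id]]
  trn <- node$train_idx; val <- node$val_idx
  y_val <- task$label[val]
  if (length(unique(y_val)) < 2) return(NULL)
  if (length(trn) < 2 * config$min_child_training_size) return(NULL)
  incumbent <- node$val_auc
  path <- root_path(tree, node_id)
  sources <- c(path, ".self")
  kinds <- config$learner_set
  mpc <- config$min_child_validation_per_class
  xt <- matrix$values[trn, , drop = FALSE]
  xv <- matrix$values[val, , drop = FALSE]
  probs <- seq_len(config$quantile_count - 1) / config$quantile_count

  best <- NULL
  for (ci in seq_len(ncol(xt))) {
    taus <- unique(stats::quantile(xt[, ci], probs = probs, names = FALSE,
                                   type = 7))
    for (tau in taus) {
      lt <- trn[xt[, ci] < tau]; rt <- trn[xt[, ci] >= tau]
      if (length(lt) < config$min_child_training_size ||
          length(rt) < config$min_child_training_size) next
      lv <- val[xv[, ci] < tau]; rv <- val[xv[, ci] >= tau]
      yl <- task$label[lv]; yr <- task$label[rv]
      if (sum(yl == 1) < mpc || sum(yl == 0) < mpc ||
          sum(yr == 1) < mpc || sum(yr == 0) < mpc) next

      side <- function(child_trn, child_val) {
        models <- vector("list", 0); keys <- character(0)
        scores <- NULL
        for (kind in kinds) for (src in sources) {
          m <- if (src == ".self")
            tryCatch(fit_base_learner(kind, matrix, table, task, child_trn,
                                      node_id = ".self"),
                     error = function(e) NULL)
          else node_model(tree, src, kind, matrix, table, task)
          if (is.null(m)) next
          s <- predict_risk(m, matrix, child_val)
          models[[length(models) + 1L]] <- list(kind = kind, source = src,
                                                model = m)
          scores <- cbind(scores, s)
        }
        list(models = models, scores = scores)
      }
      L <- side(lt, lv); R <- side(rt, rv)
      if (length(L$models) == 0 || length(R$models) == 0) next

      y_comb <- c(yl, yr)
      # canonical order: learner left, learner right, source left, source right
      ord_key <- function(side_models)
        order(match(vapply(side_models, `[[`, "", "kind"), kinds),
              match(vapply(side_models, `[[`, "", "source"), sources))
      for (i in ord_key(L$models)) for (j in ord_key(R$models)) {
        a <- auc(c(L$scores[, i], R$scores[, j]), y_comb)
        if (is.null(best) || a > best$auc) {
          best <- list(node_id = node_id, col_index = ci,
                       feature = colnames(matrix$values)[ci],
                       threshold = tau, auc = a, auc_before = incumbent,
                       left = c(L$models[[i]],
                                list(train_idx = lt, val_idx = lv)),
                       right = c(R$models[[j]],
                                 list(train_idx = rt, val_idx = rv)))
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  if (best$auc <= incumbent + config$improvement_epsilon) return(NULL)
  best$delta <- best$auc - best$auc_before
  best
}

# incumbent validation AUC of a node's model over its validation members;
# NA when undefined (single-class validation membership)
node_val_auc <- function(model, matrix, task, val_idx) {
  y <- task$label[val_idx]
  if (length(unique(y)) < 2) return(NA_real_)
  auc(predict_risk(model, matrix, val_idx), y)
}

top3_features <- function(matrix, task, idx) {
  sc <- tryCatch(relevance_scores(matrix, task, idx), error = function(e) NULL)
  if (is.null(sc)) return(character(0))
  names(sort(sc, decreasing = TRUE))[seq_len(min(3, length(sc)))]
}

#' Build a tree of predictors
#'
#' Recursive construction. Stage 0 trains every learner of the base class on
#' the full training part and assigns to the root the one with the highest
#' validation AUC. Each later stage searches every terminal node for its best
#' admissible split (\code{\link{search_best_split}}) and accepts the single
#' split with the largest validation-AUC improvement over its node's
#' incumbent model, provided the overall tree validation AUC does not
#' decrease; children inherit the winning side models and their training-node
#' provenance. Construction stops when no terminal admits an improving split.
#' Finally \code{\link{fit_path_weights}} fits the per-terminal path weights.
#' Fully deterministic given \code{config$seed}.
#'
#' @param matrix a completed \code{feature_matrix}.
#' @param table the \code{cohort_table}.
#' @param task the \code{horizon_task}.
#' @param config a \code{build_config}.
#' @return a \code{tops_tree}.
#' @export
build_tops <- function(matrix, table, task, config = build_config()) {
  n_inc <- sum(task$included)
  if (n_inc < 2 * config$min_child_training_size)
    stop("too few included subjects for the configured size floors")
  sp <- split_development(task, config$validation_fraction, config$seed)
  trn <- sp$train; val <- sp$validation

  tree <- list(nodes = list(), root_id = "n1", horizon = task$horizon,
               columns = colnames(matrix$values), config = config,
               train_idx = trn, val_idx = val,
               path_weights = list(), build_log = NULL)
  tree$cache <- new.env(parent = emptyenv())
  tree$nodes[["n1"]] <- list(node_id = "n1", parent_id = NULL, depth = 0L,
                             constraints = NULL, split = NULL,
                             child_ids = NULL, train_idx = trn, val_idx = val,
                             n_train = length(trn), n_val = length(val))

  # Stage 0: globally trained learners compete on the validation part
  root <- NULL
  for (kind in config$learner_set) {
    m <- node_model(tree, "n1", kind, matrix, table, task)
    if (is.null(m)) next
    a <- node_val_auc(m, matrix, task, val)
    if (is.null(root) || isTRUE(a > root$auc) ||
        (is.na(root$auc) && !is.na(a)))
      root <- list(model = m, auc = a)
  }
  if (is.null(root)) stop("no base learner could be fitted at the root")
  tree$nodes[["n1"]]$model <- root$model
  tree$nodes[["n1"]]$training_node_id <- "n1"
  tree$nodes[["n1"]]$val_auc <- root$auc
  tree$nodes[["n1"]]$top_features <- top3_features(matrix, task, trn)

  y_all <- task$label[val]
  scores_val <- predict_risk(root$model, matrix, val)
  overall_auc <- auc(scores_val, y_all)
  log_rows <- list(list(stage = 0L, node = "n1", feature = NA_character_,
                        threshold = NA_real_, learner_left = NA_character_,
                        learner_right = NA_character_,
                        train_node_left = NA_character_,
                        train_node_right = NA_character_,
                        auc_node_before = NA_real_, auc_node_after = root$auc,
                        auc_tree = overall_auc))

  pending <- list()
  pending[["n1"]] <- search_best_split(tree, "n1", matrix, table, task, config)
  next_id <- 2L
  stage <- 0L

  repeat {
    live <- Filter(Negate(is.null), pending)
    if (length(live) == 0) break
    deltas <- vapply(live, `[[`, numeric(1), "delta")
    accepted <- NULL; new_scores <- NULL; new_overall <- NA_real_
    for (k in order(-deltas)) {
      cand <- live[[k]]
      ns <- scores_val
      ns[match(cand$left$val_idx, val)] <-
        predict_risk(cand$left$model, matrix, cand$left$val_idx)
      ns[match(cand$right$val_idx, val)] <-
        predict_risk(cand$right$model, matrix, cand$right$val_idx)
      oa <- auc(ns, y_all)
      if (oa >= overall_auc - 1e-12) {
        accepted <- cand; new_scores <- ns; new_overall <- oa
        break
      }
    }
    if (is.null(accepted)) break

    stage <- stage + 1L
    pid <- accepted$node_id
    parent <- tree$nodes[[pid]]
    ids <- paste0("n", c(next_id, next_id + 1L)); next_id <- next_id + 2L
    sides <- list(accepted$left, accepted$right)
    ops <- c("<", ">=")
    for (s in 1:2) {
      sd <- sides[[s]]
      model <- sd$model
      tnid <- if (sd$source == ".self") ids[s] else sd$source
      model$training_node_id <- tnid
      con <- rbind(parent$constraints,
                   data.frame(feature = accepted$feature, op = ops[s],
                              threshold = accepted$threshold,
                              stringsAsFactors = FALSE))
      tree$nodes[[ids[s]]] <- list(
        node_id = ids[s], parent_id = pid, depth = parent$depth + 1L,
        constraints = con, split = NULL, child_ids = NULL,
        train_idx = sd$train_idx, val_idx = sd$val_idx,
        n_train = length(sd$train_idx), n_val = length(sd$val_idx),
        model = model, training_node_id = tnid,
        val_auc = node_val_auc(model, matrix, task, sd$val_idx),
        top_features = top3_features(matrix, task, sd$train_idx))
    }
    tree$nodes[[pid]]$split <- list(feature = accepted$feature,
                                    threshold = accepted$threshold)
    tree$nodes[[pid]]$child_ids <- ids
    log_rows[[length(log_rows) + 1L]] <- list(
      stage = stage, node = pid, feature = accepted$feature,
      threshold = accepted$threshold,
      learner_left = accepted$left$kind, learner_right = accepted$right$kind,
      train_node_left = tree$nodes[[ids[1]]]$training_node_id,
      train_node_right = tree$nodes[[ids[2]]]$training_node_id,
      auc_node_before = accepted$auc_before, auc_node_after = accepted$auc,
      auc_tree = new_overall)
    scores_val <- new_scores; overall_auc <- new_overall
    pending[[pid]] <- NULL
    for (cid in ids) {
      pending[[cid]] <- if (tree$nodes[[cid]]$depth < config$max_depth)
        search_best_split(tree, cid, matrix, table, task, config) else NULL
    }
  }

  tree$build_log <- do.call(rbind, lapply(log_rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  class(tree) <- "tops_tree"
  tree <- fit_path_weights(tree, matrix, task, tree$val_idx)
  tree
}

#' Fit path weights for every terminal node
#'
#' For each terminal node, regresses the binary labels of its validation
#' members on the risk scores produced by each model along its root-path,
#' under non-negativity (NNLS), and normalizes the weights to the simplex so
#' the path-averaged prediction stays in [0, 1]. Terminals with fewer than 10
#' validation members, or an all-zero NNLS solution (e.g. collinear path
#' scores), fall back to uniform weights over the path.
#'
#' @param tree a built \code{tops_tree}.
#' @param matrix,task the development data.
#' @param validation_idx validation subject indices (default: the tree's).
#' @return the tree with \code{path_weights} populated.
#' @export
fit_path_weights <- function(tree, matrix, task,
                             validation_idx = tree$val_idx) {
  terminals <- names(Filter(function(n) is.null(n$child_ids), tree$nodes))
  for (tid in terminals) {
    path <- root_path(tree, tid)
    vm <- intersect(tree$nodes[[tid]]$val_idx, validation_idx)
    w <- rep(1 / length(path), length(path))
    if (length(vm) >= 10 && length(path) > 1) {
      S <- vapply(path, function(nid)
        predict_risk(tree$nodes[[nid]]$model, matrix, vm),
        numeric(length(vm)))
      y <- task$label[vm]
      collinear <- all(abs(S - S[, 1]) < 1e-12)
      if (!collinear) {
        sol <- tryCatch(pracma::lsqnonneg(S, y)$x, error = function(e) NULL)
        if (!is.null(sol) && sum(sol) > 0) w <- sol / sum(sol)
      }
    }
    names(w) <- path
    tree$path_weights[[tid]] <- w
  }
  tree
}

# terminal node id for each row of a plain numeric matrix
route_to_terminal <- function(tree, m) {
  out <- character(nrow(m))
  rows <- seq_len(nrow(m))
  recurse <- function(nid, rows) {
    node <- tree$nodes[[nid]]
    if (is.null(node$child_ids)) { out[rows] <<- nid; return(invisible()) }
    xcol <- m[rows, node$split$feature]
    left <- xcol < node$split$threshold
    if (any(left)) recurse(node$child_ids[1], rows[left])
    if (any(!left)) recurse(node$child_ids[2], rows[!left])
  }
  if (length(rows)) recurse(tree$root_id, rows)
  out
}

as_plain_matrix <- function(tree, newdata) {
  m <- if (inherits(newdata, "feature_matrix")) newdata$values
       else if (is.matrix(newdata)) newdata
       else matrix(newdata, nrow = 1, dimnames = list(NULL, names(newdata)))
  if (!identical(colnames(m), tree$columns)) {
    missing <- setdiff(tree$columns, colnames(m))
    extra <- setdiff(colnames(m), tree$columns)
    stop(sprintf("column mismatch: missing [%s], extra [%s]",
                 paste(missing, collapse = ", "),
                 paste(extra, collapse = ", ")))
  }
  m
}

#' Predict horizon mortality risk with a tree of predictors
#'
#' Routes each subject to its terminal node and returns the path-weighted
#' average of the predictions of the models along the root-to-terminal path.
#' Lies in [0, 1] because the weights lie on the simplex and every base model
#' scores in [0, 1].
#'
#' @param tree a built \code{tops_tree}.
#' @param newdata a \code{feature_matrix}, a numeric matrix with the tree's
#'   columns, or a single named feature vector.
#' @return numeric risk scores in [0, 1], one per subject.
#' @export
predict_tops <- function(tree, newdata) {
  m <- as_plain_matrix(tree, newdata)
  fm <- structure(list(values = m), class = "feature_matrix")
  term <- route_to_terminal(tree, m)
  out <- numeric(nrow(m))
  for (tid in unique(term)) {
    rows <- which(term == tid)
    w <- tree$path_weights[[tid]]
    h <- numeric(length(rows))
    for (nid in names(w))
      h <- h + w[[nid]] * predict_risk(tree$nodes[[nid]]$model, fm, rows)
    out[rows] <- h
  }
  out
}

#' @export
predict.tops_tree <- function(object, newdata, ...) predict_tops(object, newdata)

#' @export
print.tops_tree <- function(x, ...) {
  nt <- sum(vapply(x$nodes, function(n) is.null(n$child_ids), logical(1)))
  cat(sprintf("tops_tree: horizon %g days, %d nodes (%d terminal), %d accepted splits\n",
              x$horizon, length(x$nodes), nt, max(x$build_log$stage)))
  invisible(x)
}

#' Piecewise survival function from horizon-specific trees
#'
#' Evaluates one subject's predicted risk under each horizon's tree, converts
#' to survival (1 - risk), enforces monotone non-increase across horizons by
#' isotonic (pool-adjacent-violators) adjustment, anchors S(0) = 1 and
#' interpolates linearly in time between horizons (constant beyond the last).
#'
#' @param trees list of \code{tops_tree} objects built at distinct horizons.
#' @param x a single named feature vector (or 1-row matrix).
#' @return a \code{tops_survival_curve}: list with \code{times},
#'   \code{survival} and an evaluator \code{fn(t)}.
#' @export
survival_curve <- function(trees, x) {
  if (length(trees) < 2) stop("need >= 2 horizons")
  h <- vapply(trees, `[[`, numeric(1), "horizon")
  ord <- order(h); h <- h[ord]; trees <- trees[ord]
  if (anyDuplicated(h)) stop("duplicate horizons")
  s <- vapply(trees, function(tr) 1 - predict_tops(tr, x)[1], numeric(1))
  s_adj <- -stats::isoreg(h, -s)$yf          # non-increasing adjustment
  times <- c(0, h); surv <- c(1, s_adj)
  fn <- stats::approxfun(times, surv, rule = 2)
  structure(list(times = times, survival = surv, fn = fn),
            class = "tops_survival_curve")
}

#' @export
print.tops_survival_curve <- function(x, ...) {
  cat("survival curve at horizons (days):\n")
  print(stats::setNames(round(x$survival, 4), x$times))
  invisible(x)
}
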