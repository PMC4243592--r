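#' Fit the random-forest regressor underlying a rule ensemble
#'
#' Thin, reproducible wrapper around [randomForest::randomForest()] for
#' regression. The returned handle carries the per-tree split structure
#' (extracted once with [randomForest::getTree()]) together with a tree-major
#' index of all leaves, which later stages use to enumerate rules and to
#' encode samples into rule space.
#'
#' @param x feature matrix, data frame or [as_dataset()] object.
#' @param y numeric target vector (ignored when `x` is a dataset).
#' @param n_trees number of trees in the forest.
#' @param min_samples_leaf minimum size of terminal nodes
#'   (`nodesize` in randomForest terms).
#' @param max_features fraction of features tried at each split (in (0, 1]),
#'   or `"all"`. The default 1/3 is standard regression-forest practice.
#' @param seed integer seed making the forest reproducible; `NULL` leaves the
#'   RNG stream alone.
#' @return An object of class `"rule_forest"`: the fitted forest plus its
#'   leaf index. `n_leaves(forest)` gives the total leaf count q.
#' @examples
#' d <- make_artificial(n_per_class = 20, seed = 1)
#' f <- fit_forest(d, n_trees = 25, seed = 1)
#' f
#' @export
fit_forest <- function(x, y = NULL, n_trees = 500, min_samples_leaf = 5,
                       max_features = 1 / 3, seed = NULL) {
  if (inherits(x, "dataset")) {
    y <- x$y
    x <- x$x
  }
  x <- dataset_x(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  if (n_trees < 1) stop2("`n_trees` must be >= 1")
  if (min_samples_leaf < 1) stop2("`min_samples_leaf` must be >= 1")
  if (nrow(x) < min_samples_leaf) {
    stop2("fewer samples (", nrow(x), ") than `min_samples_leaf` (",
          min_samples_leaf, ")")
  }
  p <- ncol(x)
  mtry <- if (identical(max_features, "all")) {
    p
  } else {
    if (!is.numeric(max_features) || max_features <= 0 || max_features > 1) {
      stop2("`max_features` must be in (0, 1] or \"all\"")
    }
    max(1L, floor(p * max_features))
  }
  rf <- with_seed(seed, randomForest::randomForest(
    x, y, ntree = n_trees, nodesize = min_samples_leaf, mtry = mtry
  ))
  # per-tree split structure, as in randomForest::getTree() but robust to
  # single-node trees (where getTree() drops the matrix to a vector)
  fr <- rf$forest
  trees <- lapply(seq_len(n_trees), function(k) {
    nn <- fr$ndbigtree[k]
    tr <- cbind(
      fr$leftDaughter[seq_len(nn), k], fr$rightDaughter[seq_len(nn), k],
      fr$bestvar[seq_len(nn), k], fr$xbestsplit[seq_len(nn), k],
      fr$nodestatus[seq_len(nn), k], fr$nodepred[seq_len(nn), k]
    )
    colnames(tr) <- c("left daughter", "right daughter", "split var",
                      "split point", "status", "prediction")
    storage.mode(tr) <- "double"
    tr
  })
  leaves_per_tree <- vapply(trees, function(tr) sum(tr[, "status"] == -1), 0)
  # tree-major rule index: column j of the rule matrix <-> row j here
  leaf_index <- do.call(rbind, lapply(seq_len(n_trees), function(k) {
    tr <- trees[[k]]
    rows <- which(tr[, "status"] == -1)
    cbind(tree = k, node = rows, value = tr[rows, "prediction"])
  }))
  structure(
    list(rf = rf, trees = trees, leaf_index = leaf_index,
         leaves_per_tree = leaves_per_tree,
         feature_names = colnames(x), n_features = p,
         config = list(n_trees = n_trees, min_samples_leaf = min_samples_leaf,
                       max_features = max_features, seed = seed)),
    class = "rule_forest"
  )
}

#' Total number of leaves (rules) in a forest
#' @param forest a `"rule_forest"` object.
#' @return Integer: the total leaf count across all trees.
#' @export
n_leaves <- function(forest) {
  stopifnot(inherits(forest, "rule_forest"))
  nrow(forest$leaf_index)
}

#' @export
print.rule_forest <- function(x, ...) {
  cat("<rule_forest> ", x$config$n_trees, " trees, ", n_leaves(x),
      " leaves, ", x$n_features, " features\n", sep = "")
  invisible(x)
}

#' @export
predict.rule_forest <- function(object, newdata, ...) {
  newx <- dataset_x(if (inherits(newdata, "dataset")) newdata$x else newdata)
  as.numeric(stats::predict(object$rf, newx))
}

# l x n_trees matrix of terminal-node rows (indices into getTree output)
forest_nodes <- function(forest, x) {
  x <- dataset_x(x)
  if (ncol(x) != forest$n_features) {
    stop2("data has ", ncol(x), " features but forest was grown on ",
          forest$n_features)
  }
  colnames(x) <- forest$feature_names
  pr <- stats::predict(forest$rf, x, nodes = TRUE)
  nd <- attr(pr, "nodes")
  storage.mode(nd) <- "integer"
  nd
}
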