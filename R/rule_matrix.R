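#' Encode samples into rule space
#'
#' Maps samples to the rule-space representation: entry (i, j) equals the
#' leaf value of rule j when sample i satisfies rule j's conjunction, and 0
#' otherwise. Because a leaf value can itself be 0, coverage is tracked in a
#' separate boolean pattern matrix alongside the numeric matrix, so
#' membership never depends on the numeric value.
#'
#' When `forest` is supplied and the rules carry their (tree, leaf)
#' provenance, samples are routed down the stored trees (fast path);
#' otherwise each rule's conditions are evaluated directly. Both paths give
#' identical encodings.
#'
#' @param x feature matrix, data frame or [as_dataset()] object.
#' @param rules a `"rule_set"`.
#' @param forest optional `"rule_forest"` the rules came from.
#' @return An object of class `"rule_matrix"`: list with `values` (sparse
#'   l x q numeric matrix), `coverage` (sparse logical pattern), `n`, `q`.
#' @examples
#' d <- make_artificial(n_per_class = 20, seed = 1)
#' f <- fit_forest(d, n_trees = 10, seed = 1)
#' rs <- extract_rules(f)
#' rm <- rule_matrix(d, rs, forest = f)
#' # row sums / n_trees reproduce the forest's own predictions
#' max(abs(Matrix::rowSums(rm$values) / 10 - predict(f, d)))
#' @export
rule_matrix <- function(x, rules, forest = NULL) {
  stopifnot(inherits(rules, "rule_set"))
  x <- dataset_x(if (inherits(x, "dataset")) x$x else x)
  if (ncol(x) != rules$n_features) {
    stop2("data has ", ncol(x), " features but rules were built on ",
          rules$n_features)
  }
  l <- nrow(x)
  q <- length(rules)
  if (!is.null(forest)) {
    stopifnot(inherits(forest, "rule_forest"))
    nd <- forest_nodes(forest, x)
    # map (tree, node) -> rule column
    keys <- rules$info$tree * (max(forest$leaf_index[, "node"]) + 1) +
      rules$info$leaf
    ii <- jj <- vector("list", length(unique(rules$info$tree)))
    trees <- unique(rules$info$tree)
    for (t in seq_along(trees)) {
      k <- trees[[t]]
      hit <- match(k * (max(forest$leaf_index[, "node"]) + 1) + nd[, k], keys)
      obs <- which(!is.na(hit))
      ii[[t]] <- obs
      jj[[t]] <- hit[obs]
    }
    i <- unlist(ii)
    j <- unlist(jj)
  } else {
    ii <- vector("list", q)
    for (r in seq_len(q)) {
      cn <- rules$conditions[rules$conditions$rule == r, , drop = FALSE]
      sat <- rep(TRUE, l)
      for (cidx in seq_len(nrow(cn))) {
        v <- x[, cn$feature[cidx]]
        sat <- sat &
          if (cn$op[cidx] == "<=") v <= cn$threshold[cidx] else v > cn$threshold[cidx]
      }
      ii[[r]] <- which(sat)
    }
    i <- unlist(ii)
    j <- rep.int(seq_len(q), vapply(ii, length, 0L))
  }
  coverage <- Matrix::sparseMatrix(i = i, j = j, dims = c(l, q))
  values <- Matrix::sparseMatrix(i = i, j = j, x = rules$info$value[j],
                                 dims = c(l, q))
  structure(list(values = values, coverage = coverage, n = l, q = q),
            class = "rule_matrix")
}

#' @export
print.rule_matrix <- function(x, ...) {
  cat("<rule_matrix> ", x$n, " samples x ", x$q, " rules; ",
      sum(x$coverage), " covered entries\n", sep = "")
  invisible(x)
}

# numeric matrix handed to the LP / predictions
rm_values <- function(x) {
  if (inherits(x, "rule_matrix")) return(x$values)
  if (is.matrix(x)) return(methods::as(x, "CsparseMatrix"))
  if (inherits(x, "sparseMatrix")) return(x)
  stop2("expected a rule_matrix, matrix or sparse Matrix")
}
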