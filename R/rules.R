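#' Construct a single regression rule
#'
#' A regression rule is a conjunction of single-feature threshold conditions
#' paired with a constant prediction (the leaf value). Rules are normally
#' produced by [extract_rules()]; this constructor exists for building rule
#' objects directly, e.g. published rule listings.
#'
#' @param feature integer vector of feature indices (1-based), one per
#'   condition. May be empty for the vacuous rule.
#' @param op character vector of comparison operators, `"<="` or `">"`.
#' @param threshold numeric vector of split thresholds.
#' @param value the rule's predicted target value (the leaf value).
#' @param tree,leaf provenance of the rule inside a forest (optional).
#' @return An object of class `"rule"`.
#' @examples
#' r <- rule(feature = c(2, 1), op = c("<=", ">"),
#'           threshold = c(2.04, 3.84), value = 5)
#' rule_covers(r, c(4.0, 1.0))
#' @export
rule <- function(feature = integer(), op = character(),
                 threshold = numeric(), value, tree = NA_integer_,
                 leaf = NA_integer_) {
  feature <- as.integer(feature)
  op <- as.character(op)
  threshold <- as.numeric(threshold)
  if (length(feature) != length(op) || length(op) != length(threshold)) {
    stop2("`feature`, `op` and `threshold` must have equal length")
  }
  if (!all(op %in% c("<=", ">"))) stop2("`op` entries must be \"<=\" or \">\"")
  structure(
    list(conditions = data.frame(feature = feature, op = op,
                                 threshold = threshold),
         value = as.numeric(value), tree = as.integer(tree),
         leaf = as.integer(leaf)),
    class = "rule"
  )
}

#' @export
print.rule <- function(x, digits = 2, ...) {
  cat(format_rule_string(x$conditions, x$value, NULL, digits), "\n")
  invisible(x)
}

#' Does a rule cover a sample?
#'
#' Tests whether a sample satisfies every condition of a rule's conjunction.
#' A rule with no conditions covers everything.
#'
#' @param rule a `"rule"` object.
#' @param x numeric vector with one entry per feature, or a matrix with
#'   samples in rows.
#' @return Logical, one value per sample.
#' @export
rule_covers <- function(rule, x) {
  stopifnot(inherits(rule, "rule"))
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  x <- dataset_x(x)
  cn <- rule$conditions
  if (nrow(cn) && max(cn$feature) > ncol(x)) {
    stop2("rule references feature ", max(cn$feature),
          " but sample has only ", ncol(x))
  }
  out <- rep(TRUE, nrow(x))
  for (i in seq_len(nrow(cn))) {
    v <- x[, cn$feature[i]]
    out <- out & if (cn$op[i] == "<=") v <= cn$threshold[i] else v > cn$threshold[i]
  }
  out
}

#' Enumerate all root-to-leaf rules of a forest
#'
#' Every path from the root to a leaf of every tree becomes one regression
#' rule: the conjunction of the split tests along the path, predicting the
#' leaf's value. Repeated splits on one feature along a path are intersected
#' into a single interval (at most one `"<="` and one `">"` condition per
#' feature), so the printed rules are compact; thresholds keep full float
#' precision. Rules are ordered tree-major, then by leaf node id, so rule j
#' here is column j of the rule matrix.
#'
#' @param forest a `"rule_forest"` from [fit_forest()].
#' @return An object of class `"rule_set"` with `q = n_leaves(forest)` rules.
#' @export
extract_rules <- function(forest) {
  stopifnot(inherits(forest, "rule_forest"))
  parts <- vector("list", length(forest$trees))
  offset <- 0L
  for (k in seq_along(forest$trees)) {
    tr <- forest$trees[[k]]
    nn <- nrow(tr)
    leaves <- which(tr[, "status"] == -1)
    parent <- integer(nn)
    side <- integer(nn) # 0 = left (<=), 1 = right (>)
    internal <- which(tr[, "status"] != -1)
    parent[tr[internal, 1L]] <- internal
    parent[tr[internal, 2L]] <- internal
    side[tr[internal, 2L]] <- 1L
    # walk all leaves towards the root simultaneously
    rid <- seq_along(leaves)
    cur <- leaves
    rl <- fl <- ol <- list(); tl <- dl <- list()
    depth <- 0L
    while (length(cur)) {
      par <- parent[cur]
      act <- par > 0L
      if (!any(act)) break
      depth <- depth + 1L
      cur <- cur[act]; rid <- rid[act]
      par <- par[act]
      rl[[depth]] <- rid
      fl[[depth]] <- tr[par, "split var"]
      ol[[depth]] <- side[cur]
      tl[[depth]] <- tr[par, "split point"]
      dl[[depth]] <- rep.int(depth, length(cur))
      cur <- par
    }
    if (depth > 0L) {
      parts[[k]] <- data.frame(
        rule = offset + unlist(rl),
        feature = as.integer(unlist(fl)),
        op = unlist(ol),
        threshold = unlist(tl),
        up = unlist(dl) # steps above the leaf; root-to-leaf order = decreasing
      )
    }
    offset <- offset + length(leaves)
  }
  cond <- do.call(rbind, parts)
  if (is.null(cond)) {
    cond <- data.frame(rule = integer(), feature = integer(), op = integer(),
                       threshold = numeric(), up = integer())
  }
  cond <- simplify_conditions(cond, forest$n_features)
  structure(
    list(conditions = cond,
         info = data.frame(tree = as.integer(forest$leaf_index[, "tree"]),
                           leaf = as.integer(forest$leaf_index[, "node"]),
                           value = forest$leaf_index[, "value"]),
         feature_names = forest$feature_names,
         n_features = forest$n_features),
    class = "rule_set"
  )
}

# Intersect repeated splits on one feature into a single interval:
# keep the min "<=" threshold and the max ">" threshold per (rule, feature).
# `up` counts steps above the leaf, so path (root-to-leaf) position is -up.
simplify_conditions <- function(cond, p) {
  if (nrow(cond) == 0L) {
    return(data.frame(rule = integer(), feature = integer(),
                      op = character(), threshold = numeric()))
  }
  key <- (cond$rule - 1) * (2 * p) + (cond$feature - 1) * 2 + cond$op
  # binding threshold: min for "<=" (op 0), max for ">" (op 1)
  eff <- ifelse(cond$op == 0L, cond$threshold, -cond$threshold)
  o <- order(key, eff)
  first <- !duplicated(key[o])
  picked <- o[first]
  # path position of the first occurrence of each (rule, feature, op)
  o2 <- order(key, -cond$up)
  first2 <- !duplicated(key[o2])
  pos <- cond$up[o2[first2]] # aligned with sorted unique keys
  res <- data.frame(rule = cond$rule[picked],
                    feature = cond$feature[picked],
                    op = c("<=", ">")[cond$op[picked] + 1L],
                    threshold = cond$threshold[picked],
                    pos = -pos)
  res <- res[order(res$rule, res$pos), c("rule", "feature", "op", "threshold")]
  rownames(res) <- NULL
  res
}

#' Assemble a rule set from individual rules
#'
#' @param rules list of [rule()] objects.
#' @param feature_names character vector naming the feature space the rules
#'   live in.
#' @return A `"rule_set"`.
#' @export
as_rule_set <- function(rules, feature_names) {
  stopifnot(all(vapply(rules, inherits, TRUE, "rule")))
  cond <- do.call(rbind, lapply(seq_along(rules), function(i) {
    cn <- rules[[i]]$conditions
    if (nrow(cn) == 0L) return(NULL)
    cbind(rule = i, cn)
  }))
  if (is.null(cond)) {
    cond <- data.frame(rule = integer(), feature = integer(),
                       op = character(), threshold = numeric())
  }
  structure(
    list(conditions = cond,
         info = data.frame(
           tree = vapply(rules, function(r) r$tree, 1L),
           leaf = vapply(rules, function(r) r$leaf, 1L),
           value = vapply(rules, function(r) r$value, 1)),
         feature_names = feature_names,
         n_features = length(feature_names)),
    class = "rule_set"
  )
}

#' @export
length.rule_set <- function(x) nrow(x$info)

#' @export
`[.rule_set` <- function(x, i, ...) {
  idx <- seq_len(length(x))[i]
  cn <- x$conditions[x$conditions$rule %in% idx, , drop = FALSE]
  cn$rule <- match(cn$rule, idx)
  cn <- cn[order(cn$rule), , drop = FALSE]
  rownames(cn) <- NULL
  structure(
    list(conditions = cn, info = x$info[idx, , drop = FALSE],
         feature_names = x$feature_names, n_features = x$n_features),
    class = "rule_set"
  )
}

#' @export
`[[.rule_set` <- function(x, i, ...) {
  stopifnot(length(i) == 1L, i >= 1L, i <= length(x))
  cn <- x$conditions[x$conditions$rule == i, c("feature", "op", "threshold"),
                     drop = FALSE]
  rownames(cn) <- NULL
  structure(
    list(conditions = cn, value = x$info$value[i],
         tree = x$info$tree[i], leaf = x$info$leaf[i]),
    class = "rule"
  )
}

#' @export
print.rule_set <- function(x, n = 6, digits = 2, ...) {
  q <- length(x)
  cat("<rule_set> ", q, " rules over ", x$n_features, " features\n", sep = "")
  for (i in seq_len(min(n, q))) {
    cat(sprintf("%4d: %s\n", i, format_rules(x[i], digits = digits)))
  }
  if (q > n) cat("  ... and", q - n, "more\n")
  invisible(x)
}

format_rule_string <- function(cond, value, feature_names, digits) {
  fmt <- paste0("%.", digits, "f")
  lhs <- if (nrow(cond) == 0L) {
    "TRUE"
  } else {
    nm <- if (is.null(feature_names)) {
      paste0("x", cond$feature)
    } else {
      feature_names[cond$feature]
    }
    paste(paste(nm, cond$op, sprintf(fmt, cond$threshold)), collapse = " AND ")
  }
  paste0("IF ", lhs, " THEN y = ", sprintf(fmt, value))
}

#' Format rules as IF-THEN text
#'
#' One line per rule in the style `IF x2 <= 2.04 AND x1 > 3.84 THEN y = 5.00`.
#' Thresholds are rounded for display only; the underlying rule set keeps
#' full precision.
#'
#' @param rules a `"rule_set"`.
#' @param digits decimal places for thresholds and leaf values.
#' @param weights optional numeric vector of rule weights to prefix.
#' @return Character vector, one element per rule.
#' @export
format_rules <- function(rules, digits = 2, weights = NULL) {
  stopifnot(inherits(rules, "rule_set"))
  out <- vapply(seq_len(length(rules)), function(i) {
    cn <- rules$conditions[rules$conditions$rule == i, , drop = FALSE]
    format_rule_string(cn, rules$info$value[i], rules$feature_names, digits)
  }, character(1))
  if (!is.null(weights)) {
    out <- paste0(sprintf(paste0("w = %+.", digits, "f: "), weights), out)
  }
  out
}

#' Count rule occurrences per feature
#'
#' For each feature, counts the number of rules whose condition list
#' references it; a feature referenced twice in one rule (an interval)
#' counts once.
#'
#' @param rules a `"rule_set"`, `"rule_model"`, or list of [rule()] objects.
#' @return Named integer vector of counts, one entry per feature of the rule
#'   set's feature space.
#' @export
feature_occurrence <- function(rules) {
  if (inherits(rules, "rule_model")) rules <- rules$rules
  if (is.list(rules) && !inherits(rules, "rule_set")) {
    if (length(rules) == 0L) return(integer(0))
    p <- max(vapply(rules, function(r) {
      if (nrow(r$conditions)) max(r$conditions$feature) else 0L
    }, 0L))
    rules <- as_rule_set(rules, paste0("x", seq_len(max(p, 1L))))
  }
  stopifnot(inherits(rules, "rule_set"))
  cn <- unique(rules$conditions[c("rule", "feature")])
  counts <- tabulate(cn$feature, nbins = rules$n_features)
  names(counts) <- rules$feature_names
  counts
}
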