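#' Prune zero-weight rules into a sparse rule model
#'
#' Retains exactly the rules whose LP weight magnitude exceeds the zero
#' tolerance, carrying their weights and the intercept. With the polished
#' LP solutions produced by [solve_l1_lp()], discarded weights are exactly
#' zero, so pruning leaves predictions unchanged.
#'
#' @param rules the `"rule_set"` the LP was solved over (length q).
#' @param solution an `"lp_solution"` with q weights.
#' @param zero_tolerance weights with magnitude at or below this count as
#'   zero. Default `1e-8 * max(1, max(abs(w)))`.
#' @param forest optional `"rule_forest"` attached to the model for fast
#'   prediction; dropped on serialization.
#' @return An object of class `"rule_model"`: retained `rules`, `weights`,
#'   `intercept`, `lambda`, `zero_tolerance`, `feature_names`.
#' @export
prune_rules <- function(rules, solution, zero_tolerance = NULL,
                        forest = NULL) {
  stopifnot(inherits(rules, "rule_set"), inherits(solution, "lp_solution"))
  w <- solution$weights
  if (length(w) != length(rules)) {
    stop2("solution has ", length(w), " weights but rule set has ",
          length(rules), " rules")
  }
  if (is.null(zero_tolerance)) {
    zero_tolerance <- 1e-8 * max(1, if (length(w)) max(abs(w)) else 0)
  }
  keep <- which(abs(w) > zero_tolerance)
  structure(
    list(rules = rules[keep], weights = w[keep],
         intercept = solution$intercept, lambda = solution$lambda,
         zero_tolerance = zero_tolerance,
         feature_names = rules$feature_names, forest = forest),
    class = "rule_model"
  )
}

#' @export
print.rule_model <- function(x, n = 10, digits = 2, ...) {
  k <- length(x$weights)
  cat("<rule_model> ", k, " rules, intercept = ",
      format(x$intercept, digits = 4), ", lambda = ",
      format(x$lambda, digits = 4), "\n", sep = "")
  if (k) {
    ord <- order(abs(x$weights), decreasing = TRUE)
    show <- utils::head(ord, n)
    txt <- format_rules(x$rules[show], digits = digits,
                        weights = x$weights[show])
    cat(paste0("  ", txt, collapse = "\n"), "\n")
    if (k > n) cat("  ... and", k - n, "more\n")
  }
  invisible(x)
}

#' Predict from a sparse rule model
#'
#' Encodes new samples against the retained rules (leaf value where covered,
#' 0 otherwise) and returns `w' X + b`. A sample covered by no retained rule
#' is predicted as the intercept `b`.
#'
#' @param object a `"rule_model"`.
#' @param newdata feature matrix, data frame or [as_dataset()] object.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.rule_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "dataset")) newdata$x else dataset_x(newdata)
  # align by name when the data carries extra columns (e.g. the target) or
  # a different column order
  if (!is.null(colnames(x)) && !is.null(object$feature_names) &&
      !identical(colnames(x), object$feature_names) &&
      all(object$feature_names %in% colnames(x))) {
    x <- x[, object$feature_names, drop = FALSE]
  }
  if (length(object$weights) == 0L) {
    return(rep(object$intercept, nrow(x)))
  }
  rm <- rule_matrix(x, object$rules, forest = object$forest)
  as.numeric(rm$values %*% object$weights) + object$intercept
}

#' Features referenced by a model's retained rules
#'
#' The union of feature indices over all conditions of all retained rules.
#' Features absent from every rule carry no information in the model and are
#' the ones dropped by the refinement loop.
#'
#' @param model a `"rule_model"` (or a `"rule_set"`).
#' @return Sorted integer vector of feature indices, named with the feature
#'   names.
#' @export
features_in_rules <- function(model) {
  rules <- if (inherits(model, "rule_model")) model$rules else model
  stopifnot(inherits(rules, "rule_set"))
  idx <- sort(unique(rules$conditions$feature))
  names(idx) <- rules$feature_names[idx]
  idx
}

#' Top rules by weight magnitude
#'
#' @param model a `"rule_model"`.
#' @param k number of rules to return; capped at the retained-rule count.
#' @return A list with `rules` (a `"rule_set"` ordered by decreasing
#'   `|weight|`, ties broken by tree then leaf id) and `weights`.
#' @export
top_rules <- function(model, k) {
  stopifnot(inherits(model, "rule_model"), k >= 1)
  ord <- order(-abs(model$weights), model$rules$info$tree,
               model$rules$info$leaf)
  ord <- utils::head(ord, k)
  structure(list(rules = model$rules[ord], weights = model$weights[ord]),
            class = "top_rules")
}

#' @export
print.top_rules <- function(x, digits = 2, ...) {
  cat(paste0(format_rules(x$rules, digits = digits, weights = x$weights),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Interpretability summary of a sparse rule model
#'
#' The rule-complexity metrics reported alongside accuracy: retained-rule
#' count, mean and standard deviation of the number of conditions per rule,
#' and the number of distinct features the rules reference.
#'
#' @param model a `"rule_model"`.
#' @return A list with `n_rules`, `mean_conditions_per_rule`,
#'   `sd_conditions_per_rule`, `n_features_selected`.
#' @export
interpretability_stats <- function(model) {
  stopifnot(inherits(model, "rule_model"))
  k <- length(model$weights)
  if (k == 0L) {
    return(list(n_rules = 0L, mean_conditions_per_rule = 0,
                sd_conditions_per_rule = 0, n_features_selected = 0L))
  }
  nc <- tabulate(model$rules$conditions$rule, nbins = k)
  list(n_rules = k,
       mean_conditions_per_rule = mean(nc),
       sd_conditions_per_rule = if (k > 1) stats::sd(nc) else 0,
       n_features_selected = length(features_in_rules(model)))
}
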