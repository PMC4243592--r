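#' Sparse regression rule ensembles from regularized random forests
#'
#' Fits the full pipeline: grow a random-forest regressor, enumerate every
#' root-to-leaf path as a regression rule, encode the training samples into
#' rule space (leaf value where the sample reaches the leaf, 0 otherwise),
#' select the regularization strength by cross-validation, solve the
#' 1-norm-regularized linear program over rule weights, and prune
#' zero-weight rules. With `refine = TRUE` (the default) the pipeline is
#' iterated: features that appear in no retained rule are eliminated, the
#' forest is regrown on the survivors, and the loop repeats until the
#' selected feature set stops changing (or cycles, or `max_iterations` is
#' reached).
#'
#' @param x feature matrix, data frame, [as_dataset()] object, or a formula.
#' @param y numeric target vector (when `x` is a matrix).
#' @param data a data frame (formula interface).
#' @param n_trees,min_samples_leaf,max_features forest hyperparameters, see
#'   [fit_forest()].
#' @param lambda_grid candidate regularization values; default is the
#'   data-driven [lambda_grid()] with `n_lambda` points, recomputed each
#'   iteration.
#' @param n_lambda,n_folds,cv_rule cross-validation settings, see
#'   [select_lambda_cv()].
#' @param zero_tolerance pruning tolerance, see [prune_rules()].
#' @param refine logical; iterate rule extraction and feature elimination.
#' @param max_iterations cap on refinement iterations.
#' @param seed master seed; with `seed_policy = "per-iteration"` each
#'   iteration's forest uses a seed derived from it (seed and iteration
#'   index), so the run is reproducible without artificially identical
#'   forests across iterations. `"fixed"` reuses the master seed verbatim.
#' @param trace logical; log per-iteration feature and rule counts.
#' @param formula model formula such as `y ~ .` (formula interface).
#' @param ... passed on to `ruleforest.default`.
#' @return An object of class `"ruleforest"` with components `model` (the
#'   final `"rule_model"`), `forest` (final `"rule_forest"`), `history`
#'   (one row per iteration: `iteration`, `n_features`, `n_rules`,
#'   `lambda`, `train_r2`), `converged`, `final_features`, `fitted`,
#'   `residuals`. Methods: `print`, `summary`, `coef`, `predict`, `plot`,
#'   `residuals`, `fitted`.
#' @examples
#' d <- make_artificial(n_per_class = 25, seed = 7)
#' fit <- ruleforest(d, n_trees = 40, n_lambda = 6, seed = 7)
#' fit
#' predict(fit, d)[1:5]
#' @export
ruleforest <- function(x, ...) UseMethod("ruleforest")

#' @rdname ruleforest
#' @export
ruleforest.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- as.matrix(mf[-1L])
  out <- ruleforest.default(x, y, ...)
  out$call <- match.call()
  out
}

#' @rdname ruleforest
#' @export
ruleforest.dataset <- function(x, ...) {
  out <- ruleforest.default(x$x, x$y, ...)
  out$call <- match.call()
  out
}

#' @rdname ruleforest
#' @export
ruleforest.default <- function(x, y, n_trees = 500, min_samples_leaf = 5,
                               max_features = 1 / 3, lambda_grid = NULL,
                               n_lambda = 20, n_folds = 5,
                               cv_rule = c("1se", "min"),
                               zero_tolerance = NULL, refine = TRUE,
                               max_iterations = 20, seed = NULL,
                               seed_policy = c("per-iteration", "fixed"),
                               trace = FALSE, ...) {
  seed_policy <- match.arg(seed_policy)
  cv_rule <- match.arg(cv_rule)
  x <- dataset_x(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  p <- ncol(x)
  if (!refine) max_iterations <- 1L
  if (max_iterations < 1) stop2("`max_iterations` must be >= 1")

  feat <- seq_len(p)
  prev_selected <- NULL
  seen <- list()
  hist_rows <- list()
  converged <- FALSE
  it <- 0L
  model <- forest <- cvsel <- NULL

  repeat {
    it <- it + 1L
    seed_k <- if (seed_policy == "per-iteration") derive_seed(seed, it) else seed
    forest <- fit_forest(x[, feat, drop = FALSE], y, n_trees = n_trees,
                         min_samples_leaf = min_samples_leaf,
                         max_features = max_features, seed = seed_k)
    rules <- extract_rules(forest)
    rm <- rule_matrix(x[, feat, drop = FALSE], rules, forest = forest)
    grid <- lambda_grid %||% lambda_grid(rm, y, n_lambda = n_lambda)
    cvsel <- select_lambda_cv(rm, y, grid = grid, n_folds = n_folds,
                              rule = cv_rule,
                              fold_seed = derive_seed(seed_k, 999L))
    sol <- solve_l1_lp(rm, y, cvsel$chosen_lambda)
    model <- prune_rules(rules, sol, zero_tolerance = zero_tolerance,
                         forest = forest)
    train_pred <- as.numeric(rm$values %*% sol$weights) + sol$intercept
    train_r2 <- if (stats::var(y) > 0) r_squared(y, train_pred) else NA_real_
    new_feat <- unname(feat[features_in_rules(model)])
    hist_rows[[it]] <- data.frame(
      iteration = it, n_features = length(new_feat),
      n_rules = length(model$weights), lambda = cvsel$chosen_lambda,
      train_r2 = train_r2
    )
    if (trace) {
      message(sprintf(
        "iteration %d: %d features -> %d selected, %d rules, lambda = %.4g, train R2 = %.3f",
        it, length(feat), length(new_feat), length(model$weights),
        cvsel$chosen_lambda, train_r2))
    }
    if (length(new_feat) == 0L) {
      warning("selected feature set became empty; returning the ",
              "constant-intercept model", call. = FALSE)
      break
    }
    # converged once two consecutive iterations select the same set
    if (identical(new_feat, prev_selected)) {
      converged <- TRUE
      break
    }
    if (any(vapply(seen, identical, TRUE, y = new_feat))) {
      warning("feature set cycled back to an earlier iteration's set; ",
              "stopping", call. = FALSE)
      break
    }
    if (!is.null(prev_selected)) seen <- c(seen, list(prev_selected))
    prev_selected <- new_feat
    if (it >= max_iterations) break
    feat <- new_feat
  }

  if (!refine) converged <- NA

  # express the final model in the original feature space
  if (length(feat) < p) {
    model$rules$conditions$feature <- feat[model$rules$conditions$feature]
    model$rules$feature_names <- colnames(x)
    model$rules$n_features <- p
    model$feature_names <- colnames(x)
    model$forest <- NULL # forest lives in subset space; conditions suffice
  }
  final_features <- features_in_rules(model)
  fitted <- predict(model, x)

  structure(
    list(model = model, forest = forest, history = do.call(rbind, hist_rows),
         converged = converged, iterations = it,
         final_features = final_features,
         feature_names = colnames(x), cv = cvsel,
         fitted = fitted, residuals = y - fitted, y = y,
         config = list(n_trees = n_trees,
                       min_samples_leaf = min_samples_leaf,
                       max_features = max_features, n_lambda = n_lambda,
                       n_folds = n_folds, cv_rule = cv_rule,
                       max_iterations = max_iterations,
                       seed = seed, seed_policy = seed_policy,
                       refine = refine),
         call = match.call()),
    class = "ruleforest"
  )
}

#' @export
print.ruleforest <- function(x, ...) {
  cat("Sparse rule ensemble from a regularized random forest\n\n")
  callstr <- paste(deparse(x$call), collapse = " ")
  if (nchar(callstr) > 120) callstr <- paste0(substr(callstr, 1, 117), "...")
  cat("Call: ", callstr, "\n", sep = "")
  st <- interpretability_stats(x$model)
  cat(sprintf("Iterations: %d (%s)\n", x$iterations,
              if (isTRUE(x$converged)) "converged" else
                if (is.na(x$converged)) "single pass" else "not converged"))
  cat(sprintf("Rules retained: %d of %d forest leaves (lambda = %.4g)\n",
              st$n_rules, n_leaves(x$forest), x$model$lambda))
  cat(sprintf("Features selected: %d of %d (%s)\n", st$n_features_selected,
              length(x$feature_names),
              paste(utils::head(names(x$final_features), 8), collapse = ", ")))
  if (stats::var(x$y) > 0) {
    cat(sprintf("Training R-squared: %.3f\n", r_squared(x$y, x$fitted)))
  }
  invisible(x)
}

#' @export
summary.ruleforest <- function(object, digits = 2, ...) {
  structure(list(fit = object, stats = interpretability_stats(object$model),
                 digits = digits),
            class = "summary.ruleforest")
}

#' @export
print.summary.ruleforest <- function(x, ...) {
  print(x$fit)
  st <- x$stats
  cat(sprintf("\nConditions per rule: %.2f (sd %.2f)\n",
              st$mean_conditions_per_rule, st$sd_conditions_per_rule))
  cat("\nRefinement history:\n")
  print(x$fit$history, row.names = FALSE)
  k <- length(x$fit$model$weights)
  if (k) {
    cat("\nRules (by |weight|):\n")
    tr <- top_rules(x$fit$model, k)
    cat(paste0("  ", format_rules(tr$rules, digits = x$digits,
                                  weights = tr$weights), collapse = "\n"),
        "\n")
  }
  invisible(x)
}

#' @export
coef.ruleforest <- function(object, ...) {
  m <- object$model
  w <- m$weights
  nm <- if (length(w)) {
    paste0("rule_", m$rules$info$tree, ".", m$rules$info$leaf)
  } else {
    character(0)
  }
  stats::setNames(c(m$intercept, w), c("(Intercept)", nm))
}

#' @export
predict.ruleforest <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  predict(object$model, newdata)
}

#' @export
residuals.ruleforest <- function(object, ...) object$residuals

#' @export
fitted.ruleforest <- function(object, ...) object$fitted

#' Plot refinement dynamics
#'
#' Retained-rule and selected-feature counts per refinement iteration, the
#' usual convergence diagnostic for the iterative rule-extraction /
#' feature-elimination loop.
#'
#' @param x a `"ruleforest"` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ruleforest <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mar = c(5, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(h$iteration, h$n_rules, type = "b", pch = 19,
                 xlab = "iteration", ylab = "rules retained",
                 xaxt = "n", ...)
  graphics::axis(1, at = h$iteration)
  graphics::par(new = TRUE)
  graphics::plot(h$iteration, h$n_features, type = "b", pch = 1, lty = 2,
                 axes = FALSE, xlab = "", ylab = "", col = "grey40")
  graphics::axis(4, col.axis = "grey40")
  graphics::mtext("features selected", side = 4, line = 2.5,
                  col = "grey40")
  invisible(x)
}
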