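#' Default regularization path for the rule-weight LP
#'
#' Builds a logarithmically spaced grid of `lambda` values around a
#' data-driven scale: the smallest `lambda` at which the all-zero weight
#' vector becomes optimal, estimated from the dual bound
#' `max_j |X_j' sign(y - median(y))|`. The grid spans `range[1]` to
#' `range[2]` times that scale.
#'
#' @param rule_matrix a [rule_matrix()], matrix or sparse Matrix.
#' @param targets numeric response vector.
#' @param n_lambda number of grid points.
#' @param range multiplicative span of the grid around the scale.
#' @return Increasing numeric vector of `lambda` values.
#' @export
lambda_grid <- function(rule_matrix, targets, n_lambda = 20,
                        range = c(1e-3, 1e3)) {
  X <- rm_values(rule_matrix)
  y <- as.numeric(targets)
  s0 <- sign(y - stats::median(y))
  scale <- max(abs(as.numeric(Matrix::crossprod(X, s0))))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  10^seq(log10(range[1] * scale), log10(range[2] * scale),
         length.out = n_lambda)
}

#' Choose lambda by k-fold cross-validation
#'
#' For each candidate `lambda` the LP is solved on each training fold and
#' scored by mean squared error on the held-out fold. With
#' `rule = "1se"` (the default) the chosen `lambda` is the largest value
#' whose mean held-out error is within one standard error of the minimum —
#' the standard parsimony-favouring cross-validation rule, which matches
#' the method's goal of trading a little accuracy for a much smaller rule
#' set. `rule = "min"` picks the error-minimizing `lambda` instead; in
#' both cases exact ties are broken toward the larger (sparser) value.
#'
#' @param rule_matrix a [rule_matrix()], matrix or sparse Matrix (training
#'   samples in rows).
#' @param targets numeric response vector.
#' @param grid candidate `lambda` values; default [lambda_grid()].
#' @param n_folds number of folds (between 2 and the sample count).
#' @param fold_seed integer seed for the fold assignment.
#' @param rule selection rule: `"1se"` (default) or `"min"`.
#' @param tol,maxit forwarded to [solve_l1_lp()]; CV solves use a slightly
#'   looser tolerance than the final fit since only the held-out error is
#'   consumed.
#' @return An object of class `"lambda_selection"`: `grid`, `n_folds`,
#'   `cv_score` (mean held-out MSE per grid point), `cv_se` (its standard
#'   error across folds), `chosen_lambda`, `lambda_min`, `fold_seed`,
#'   `fold_id`.
#' @export
select_lambda_cv <- function(rule_matrix, targets, grid = NULL, n_folds = 5,
                             fold_seed = NULL, rule = c("1se", "min"),
                             tol = 1e-6, maxit = 100) {
  rule <- match.arg(rule)
  X <- rm_values(rule_matrix)
  y <- as.numeric(targets)
  l <- length(y)
  if (nrow(X) != l) stop2("rule matrix rows must match targets length")
  if (n_folds < 2 || n_folds > l) {
    stop2("`n_folds` must be between 2 and the number of samples")
  }
  if (is.null(grid)) grid <- lambda_grid(X, y)
  grid <- sort(as.numeric(grid))
  if (length(grid) == 0L) stop2("`grid` must be non-empty")
  fold_id <- with_seed(fold_seed, sample(rep_len(seq_len(n_folds), l)))
  if (min(tabulate(fold_id, n_folds)) < 2) {
    stop2("each fold needs at least 2 samples; reduce `n_folds`")
  }
  scores <- matrix(NA_real_, n_folds, length(grid))
  for (f in seq_len(n_folds)) {
    tr <- fold_id != f
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[!tr, , drop = FALSE]
    ytr <- y[tr]
    yte <- y[!tr]
    # walk the path from large to small lambda, seeding each solve's
    # working set with the previous active set
    work <- NULL
    for (gi in rev(seq_along(grid))) {
      sol <- solve_l1_lp(Xtr, ytr, grid[gi], tol = tol, maxit = maxit,
                         polish = FALSE, work_init = work)
      work <- attr(sol, "work")
      pred <- as.numeric(Xte %*% sol$weights) + sol$intercept
      scores[f, gi] <- mean((yte - pred)^2)
    }
  }
  cv_score <- colMeans(scores)
  cv_se <- apply(scores, 2, stats::sd) / sqrt(n_folds)
  best <- which.min(cv_score)
  lambda_min <- max(grid[cv_score <= cv_score[best] * (1 + 1e-9)])
  chosen <- if (rule == "1se") {
    max(grid[cv_score <= cv_score[best] + cv_se[best]])
  } else {
    lambda_min
  }
  structure(
    list(grid = grid, n_folds = n_folds, cv_score = cv_score,
         cv_se = cv_se, per_fold = scores, chosen_lambda = chosen,
         lambda_min = lambda_min, rule = rule, fold_seed = fold_seed,
         fold_id = fold_id),
    class = "lambda_selection"
  )
}

#' @export
print.lambda_selection <- function(x, ...) {
  cat("<lambda_selection> ", length(x$grid), " lambdas, ", x$n_folds,
      "-fold CV (", x$rule, " rule)\n  chosen lambda = ",
      format(x$chosen_lambda),
      " (min cv mse = ", format(min(x$cv_score), digits = 4), ")\n", sep = "")
  invisible(x)
}
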