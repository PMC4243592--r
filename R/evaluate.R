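#' Coefficient of determination
#'
#' `R^2 = 1 - SSerr / SStot` with `SSerr = sum((y - y')^2)` and
#' `SStot = sum((y - mean(y))^2)`. May be negative for predictors worse than
#' the mean; errors out when the true values are constant (SStot = 0), where
#' the metric is undefined.
#'
#' @param y_true observed target values.
#' @param y_pred predicted values, same length.
#' @return A single number, at most 1.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 5)) # -1
#' @export
r_squared <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true)
  y_pred <- as.numeric(y_pred)
  if (length(y_true) == 0L || length(y_true) != length(y_pred)) {
    stop2("`y_true` and `y_pred` must have equal, non-zero length")
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    stop2("R-squared is undefined: `y_true` is constant (SStot = 0)")
  }
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Binned true-versus-predicted confusion heatmap
#'
#' Partitions the combined range of true and predicted values into
#' `n_bins` equal-width intervals, counts samples falling into each
#' (true-bin, predicted-bin) cell, and divides the count matrix by its
#' maximum entry. For a continuous target this plays the role a confusion
#' matrix plays in classification: a good model concentrates mass on the
#' diagonal.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @param n_bins number of intervals (at least 2).
#' @return An `n_bins x n_bins` numeric matrix with entries in `[0, 1]`
#'   (rows = true bins, columns = predicted bins); the raw counts are kept
#'   in the `"counts"` attribute and the bin edges in `"breaks"`.
#' @examples
#' confusion_heatmap(c(0, 0, 10, 10), c(0, 10, 10, 10), n_bins = 2)
#' @export
confusion_heatmap <- function(y_true, y_pred, n_bins = 20) {
  y_true <- as.numeric(y_true)
  y_pred <- as.numeric(y_pred)
  if (length(y_true) == 0L) stop2("no samples")
  if (length(y_true) != length(y_pred)) stop2("lengths differ")
  if (n_bins < 2) stop2("`n_bins` must be >= 2")
  rng <- range(c(y_true, y_pred))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bt <- cut(y_true, breaks, include.lowest = TRUE, labels = FALSE)
  bp <- cut(y_pred, breaks, include.lowest = TRUE, labels = FALSE)
  counts <- matrix(0L, n_bins, n_bins)
  for (i in seq_along(bt)) {
    counts[bt[i], bp[i]] <- counts[bt[i], bp[i]] + 1L
  }
  out <- counts / max(counts)
  attr(out, "counts") <- counts
  attr(out, "breaks") <- breaks
  out
}

#' Accuracy and interpretability report for a rule model
#'
#' @param model a `"rule_model"`.
#' @param x,y evaluation data (typically a held-out test split).
#' @return An object of class `"eval_report"`: `r_squared`, `n_rules`,
#'   `mean_conditions_per_rule`, `sd_conditions_per_rule`,
#'   `n_features_selected`.
#' @export
eval_report <- function(model, x, y = NULL) {
  if (inherits(x, "dataset")) {
    y <- x$y
    x <- x$x
  }
  st <- interpretability_stats(model)
  structure(
    c(list(r_squared = r_squared(y, predict(model, x))), st),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "R-squared: %.4f | rules: %d | conditions/rule: %.2f (sd %.2f) | features: %d\n",
    x$r_squared, x$n_rules, x$mean_conditions_per_rule,
    x$sd_conditions_per_rule, x$n_features_selected))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(r_squared = x$r_squared, n_rules = x$n_rules,
             mean_conditions_per_rule = x$mean_conditions_per_rule,
             sd_conditions_per_rule = x$sd_conditions_per_rule,
             n_features_selected = x$n_features_selected)
}
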