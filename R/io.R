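#' Serialize a sparse rule model to JSON
#'
#' Writes a single JSON document with a schema-version field carrying the
#' retained rules (full-precision thresholds plus tree/leaf provenance),
#' weights, intercept, lambda, tolerances, feature names and, when known,
#' the forest configuration and master seed. [load_model()] restores a
#' model that predicts bit-identically on any input. The attached forest
#' handle, if any, is not serialized; reloaded models predict through the
#' rules' conditions, which encode the same partition.
#'
#' @param model a `"rule_model"` (or a `"ruleforest"` fit, whose final
#'   model is saved).
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  extra <- NULL
  if (inherits(model, "ruleforest")) {
    extra <- list(forest_config = model$config, history = model$history)
    model <- model$model
  }
  stopifnot(inherits(model, "rule_model"))
  doc <- list(
    schema_version = 1L,
    package = "ruleforest",
    rules = list(
      conditions = model$rules$conditions,
      info = model$rules$info,
      feature_names = model$rules$feature_names
    ),
    weights = model$weights,
    intercept = model$intercept,
    lambda = model$lambda,
    zero_tolerance = model$zero_tolerance,
    feature_names = model$feature_names
  )
  if (!is.null(extra)) doc <- c(doc, extra)
  # I(17) = 17 significant digits, enough to round-trip doubles exactly
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Restore a sparse rule model written by [save_model()]
#'
#' @param path path to the JSON document.
#' @return A `"rule_model"`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop2("cannot parse model file ", path,
                          " (truncated or not JSON): ", conditionMessage(e))
                  })
  if (is.null(doc$schema_version)) stop2("not a rule model file: ", path)
  if (doc$schema_version != 1L) {
    stop2("unsupported model schema version: ", doc$schema_version)
  }
  cond <- as.data.frame(doc$rules$conditions)
  if (nrow(cond) == 0L) {
    cond <- data.frame(rule = integer(), feature = integer(),
                       op = character(), threshold = numeric())
  }
  info <- as.data.frame(doc$rules$info)
  if (nrow(info) == 0L) {
    info <- data.frame(tree = integer(), leaf = integer(), value = numeric())
  }
  rules <- structure(
    list(conditions = cond, info = info,
         feature_names = doc$rules$feature_names,
         n_features = length(doc$rules$feature_names)),
    class = "rule_set"
  )
  structure(
    list(rules = rules, weights = as.numeric(doc$weights),
         intercept = doc$intercept, lambda = doc$lambda,
         zero_tolerance = doc$zero_tolerance,
         feature_names = doc$feature_names, forest = NULL),
    class = "rule_model"
  )
}

#' Export rules as human-readable IF-THEN text
#'
#' One rule per line in the style
#' `IF x2 <= 2.04 AND x1 > 3.84 THEN y = 5.00`, most important (largest
#' `|weight|`) first when weights are available.
#'
#' @param x a `"rule_model"`, `"ruleforest"` fit, or `"rule_set"`.
#' @param file file to write to; `""` (default) prints to the console.
#' @param digits decimal places for display.
#' @return The character vector of rule lines, invisibly.
#' @export
export_rules <- function(x, file = "", digits = 2) {
  if (inherits(x, "ruleforest")) x <- x$model
  lines <- if (inherits(x, "rule_model")) {
    k <- length(x$weights)
    if (k == 0L) {
      character(0)
    } else {
      tr <- top_rules(x, k)
      format_rules(tr$rules, digits = digits, weights = tr$weights)
    }
  } else if (inherits(x, "rule_set")) {
    format_rules(x, digits = digits)
  } else {
    stop2("cannot export rules from a ", class(x)[1])
  }
  if (nzchar(file)) {
    writeLines(lines, file)
  } else {
    cat(lines, sep = "\n")
  }
  invisible(lines)
}

#' Write the refinement history as CSV
#'
#' One row per iteration (`iteration`, `n_features`, `n_rules`, `lambda`,
#' `train_r2`), suitable for plotting the refinement dynamics.
#'
#' @param fit a `"ruleforest"` fit (or its `history` data frame).
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_history <- function(fit, path) {
  h <- if (inherits(fit, "ruleforest")) fit$history else fit
  utils::write.csv(h, path, row.names = FALSE)
  invisible(path)
}
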