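#' Construct a regression dataset
#'
#' Bundles a numeric feature matrix and a continuous target vector, after
#' validating the invariants the rest of the pipeline relies on: no missing
#' values, at least two samples, at least one feature, unique feature names.
#'
#' @param x numeric matrix or data frame of features (samples in rows).
#' @param y numeric target vector, one value per row of `x`.
#' @param feature_names optional character vector of feature names; defaults
#'   to the column names of `x` (or `x1`, `x2`, ... when absent).
#' @param target_name name of the target variable, used in printing.
#' @return An object of class `"dataset"`: a list with elements `x` (numeric
#'   matrix), `y` (numeric vector), `feature_names` and `target_name`.
#' @examples
#' d <- as_dataset(matrix(rnorm(20), 10, 2), rnorm(10))
#' d
#' @export
as_dataset <- function(x, y, feature_names = NULL, target_name = "y") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) {
    stop2("`x` has ", nrow(x), " rows but `y` has length ", length(y))
  }
  if (anyNA(x) || anyNA(y)) stop2("dataset contains missing values")
  if (nrow(x) < 2L) stop2("need at least 2 samples")
  if (ncol(x) < 1L) stop2("need at least 1 feature")
  feature_names <- feature_names %||% colnames(x) %||%
    paste0("x", seq_len(ncol(x)))
  if (anyDuplicated(feature_names)) stop2("feature names must be unique")
  if (length(feature_names) != ncol(x)) {
    stop2("`feature_names` must have one entry per feature")
  }
  colnames(x) <- feature_names
  structure(
    list(x = x, y = y, feature_names = feature_names,
         target_name = target_name),
    class = "dataset"
  )
}

#' @export
print.dataset <- function(x, ...) {
  cat("<dataset> ", nrow(x$x), " samples, ", ncol(x$x), " features; target `",
      x$target_name, "`\n", sep = "")
  cat("features:", paste(utils::head(x$feature_names, 8), collapse = ", "),
      if (length(x$feature_names) > 8) "...", "\n")
  invisible(x)
}

#' @export
as.data.frame.dataset <- function(x, ...) {
  d <- as.data.frame(x$x)
  d[[x$target_name]] <- x$y
  d
}

#' @export
dim.dataset <- function(x) dim(x$x)

#' Read a delimited table as a regression dataset
#'
#' Reads a CSV or TSV file with a header row, pulls out the designated target
#' column, and treats every remaining column as a numeric feature. The
#' delimiter is auto-detected from the header line (tab wins over comma when
#' both occur) unless forced via `sep`.
#'
#' @param path path to a delimited text file with a header row.
#' @param target name of the target column.
#' @param sep field delimiter; `NULL` (default) auto-detects comma vs tab.
#' @return A [as_dataset()] object.
#' @export
read_table <- function(path, target, sep = NULL) {
  if (!file.exists(path)) stop2("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop2("empty file: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(d) == 0L) stop2("no data rows in ", path)
  if (!target %in% names(d)) {
    stop2("target column `", target, "` not found; available columns: ",
          paste(names(d), collapse = ", "))
  }
  y <- suppressWarnings(as.numeric(d[[target]]))
  feat <- d[setdiff(names(d), target)]
  xm <- suppressWarnings(
    vapply(feat, function(col) as.numeric(col), numeric(nrow(d)))
  )
  if (!is.matrix(xm)) xm <- matrix(xm, nrow = nrow(d),
                                   dimnames = list(NULL, names(feat)))
  bad <- which(is.na(y) | rowSums(is.na(xm)) > 0)
  if (length(bad)) {
    stop2("non-numeric or missing values in data row(s): ",
          paste(utils::head(bad, 10), collapse = ", "),
          if (length(bad) > 10) " ...")
  }
  as_dataset(xm, y, feature_names = colnames(xm), target_name = target)
}

# Normalise the various inputs accepted by user-facing functions
# (dataset / data.frame+target / matrix) into a plain feature matrix.
dataset_x <- function(data) {
  if (inherits(data, "dataset")) return(data$x)
  if (is.data.frame(data)) return(as.matrix(data))
  if (is.matrix(data)) {
    storage.mode(data) <- "double"
    return(data)
  }
  if (is.numeric(data)) return(matrix(data, nrow = 1L))
  stop2("cannot interpret `data` as a feature matrix")
}
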