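#' Six-cluster nonlinear regression benchmark
#'
#' Generates the two-feature artificial dataset used throughout the
#' package's examples and tests: six isotropic Gaussian clusters, one per
#' integer target level 1..6, each contributing `n_per_class` samples with
#' the given standard deviation. The target is the (numeric) cluster label,
#' so the regression surface is a piecewise-constant, nonlinear function of
#' the two features that tree rules represent exactly.
#'
#' The default cluster means place the level-5 and level-6 clusters so that
#' the separating thresholds fall near x1 ~ 3.7-3.8, x2 ~ 1.9-2.0 and
#' x2 ~ 3.9, with inter-cluster spacing about 2 at sd 0.5. They are a
#' reconstruction chosen for that geometry (the layout is configurable),
#' not measured ground truth.
#'
#' @param n_per_class samples per target level.
#' @param sd within-cluster standard deviation.
#' @param class_means 6 x 2 matrix of cluster centres (rows = levels 1..6).
#' @param seed integer seed; two calls with the same seed are identical.
#' @return An [as_dataset()] with features `x1`, `x2` and target in
#'   `{1, ..., 6}`; the generating parameters are attached as the
#'   `"params"` attribute.
#' @examples
#' d <- make_artificial(seed = 1)
#' table(d$y)
#' @export
make_artificial <- function(n_per_class = 100, sd = 0.5,
                            class_means = artificial_means(), seed = NULL) {
  class_means <- as.matrix(class_means)
  if (!all(dim(class_means) == c(6, 2))) {
    stop2("`class_means` must be a 6 x 2 matrix")
  }
  if (sd < 0) stop2("`sd` must be non-negative")
  xy <- with_seed(seed, {
    x <- do.call(rbind, lapply(1:6, function(cl) {
      cbind(stats::rnorm(n_per_class, class_means[cl, 1], sd),
            stats::rnorm(n_per_class, class_means[cl, 2], sd))
    }))
    x
  })
  colnames(xy) <- c("x1", "x2")
  d <- as_dataset(xy, rep(1:6, each = n_per_class))
  attr(d, "params") <- list(n_per_class = n_per_class, sd = sd,
                            class_means = class_means, seed = seed)
  d
}

#' Default cluster centres for [make_artificial()]
#' @return A 6 x 2 numeric matrix.
#' @export
artificial_means <- function() {
  matrix(c(0.8, 0.8,
           0.8, 2.8,
           2.8, 2.8,
           2.9, 1.0,
           4.5, 1.0,
           1.5, 4.5), ncol = 2, byrow = TRUE)
}

#' Sparse-signal regression fixture with known ground truth
#'
#' Features are i.i.d. standard normal; the target is a sum of step
#' functions of a few randomly chosen informative features (threshold-based,
#' so tree rules can represent the truth exactly) plus Gaussian noise. The
#' informative feature set is returned for recovery scoring.
#'
#' @param n_samples,n_features dataset dimensions.
#' @param n_informative number of features carrying signal
#'   (`<= n_features`; 0 gives a pure-noise target).
#' @param effect_scale step height contributed by each informative feature.
#' @param noise_sd standard deviation of the additive target noise.
#' @param seed integer seed.
#' @return A list of class `"sparse_signal"`: `data` (an [as_dataset()]),
#'   `informative` (sorted feature indices), `thresholds`, `effects`.
#' @examples
#' sim <- make_sparse_signal(n_samples = 100, n_features = 10, seed = 1)
#' sim$informative
#' @export
make_sparse_signal <- function(n_samples = 500, n_features = 50,
                               n_informative = 3, effect_scale = 2,
                               noise_sd = 0.5, seed = NULL) {
  if (n_informative > n_features) {
    stop2("`n_informative` must be <= `n_features`")
  }
  out <- with_seed(seed, {
    x <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
    informative <- sort(sample(n_features, n_informative))
    thresholds <- stats::runif(n_informative, -0.5, 0.5)
    effects <- effect_scale * rep_len(c(1, -1), n_informative)
    signal <- rep(0, n_samples)
    for (k in seq_len(n_informative)) {
      signal <- signal + effects[k] * (x[, informative[k]] > thresholds[k])
    }
    y <- signal + stats::rnorm(n_samples, 0, noise_sd)
    list(x = x, y = y, informative = informative, thresholds = thresholds,
         effects = effects)
  })
  colnames(out$x) <- paste0("x", seq_len(n_features))
  structure(
    list(data = as_dataset(out$x, out$y),
         informative = out$informative, thresholds = out$thresholds,
         effects = out$effects, seed = seed),
    class = "sparse_signal"
  )
}

#' @export
print.sparse_signal <- function(x, ...) {
  cat("<sparse_signal> ", nrow(x$data$x), " samples, ", ncol(x$data$x),
      " features; informative: ",
      paste(x$informative, collapse = ", "), "\n", sep = "")
  invisible(x)
}
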