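#' Noise-robustness experiment
#'
#' Measures how much a method's test accuracy degrades when Gaussian noise
#' is injected into the features. For each of `n_runs` repetitions a fresh
#' train/test split is drawn; the pipeline is fitted and evaluated once on
#' clean data and once on data where every feature value of every sample is
#' independently perturbed, with probability `per_feature_probability`, by
#' adding a draw from `Normal(noise_mean, noise_sd)`. The summary statistic
#' is `D = mean(R2 clean) - mean(R2 noisy)`; smaller D means more robust.
#' A paired two-sided t-test over the per-run (clean, noisy) pairs reports
#' whether the degradation is statistically significant.
#'
#' The random-forest predictions are a byproduct of every fit, so the
#' report carries the same statistics for the forest alongside the sparse
#' rule model, allowing the robustness comparison at no extra cost.
#'
#' The split, noise, and fit seeds are drawn from separate derived streams,
#' so a no-op perturbation (`noise_sd = 0, noise_mean = 0` or
#' `per_feature_probability = 0`) reproduces the clean runs exactly and
#' gives D = 0.
#'
#' @param x,y data to experiment on (or a single [as_dataset()] as `x`).
#' @param per_feature_probability probability that a feature value is
#'   perturbed.
#' @param noise_mean,noise_sd parameters of the Gaussian noise.
#' @param n_runs number of repetitions (at least 2 for the paired test).
#' @param train_fraction fraction of samples in each training split.
#' @param noise_on which splits receive noise: `"both"` (default),
#'   `"train"`, or `"test"`.
#' @param seed master seed for the whole experiment.
#' @param ... fitting arguments forwarded to [ruleforest()].
#' @return An object of class `"noise_report"`: `mean_r2_clean`,
#'   `mean_r2_noisy`, `d_statistic`, `paired_t_p_value`, `per_run_pairs`
#'   (data frame of per-run R2 pairs), plus the same four fields for the
#'   underlying forest prefixed `forest_`.
#' @export
noise_experiment <- function(x, y = NULL, per_feature_probability = 0.3,
                             noise_mean = 0.5, noise_sd = 0.2, n_runs = 10,
                             train_fraction = 0.7,
                             noise_on = c("both", "train", "test"),
                             seed = NULL, ...) {
  noise_on <- match.arg(noise_on)
  if (inherits(x, "dataset")) {
    y <- x$y
    x <- x$x
  }
  x <- dataset_x(x)
  y <- as.numeric(y)
  if (per_feature_probability < 0 || per_feature_probability > 1) {
    stop2("`per_feature_probability` must be in [0, 1]")
  }
  if (noise_sd < 0) stop2("`noise_sd` must be non-negative")
  if (n_runs < 2) stop2("`n_runs` must be >= 2 for the paired t-test")
  l <- nrow(x)
  n_train <- max(2L, round(train_fraction * l))

  perturb <- function(m, noise_seed) {
    with_seed(noise_seed, {
      mask <- matrix(
        stats::runif(length(m)) < per_feature_probability, nrow(m), ncol(m))
      m + mask * matrix(stats::rnorm(length(m), noise_mean, noise_sd),
                        nrow(m), ncol(m))
    })
  }

  r2 <- matrix(NA_real_, n_runs, 4,
               dimnames = list(NULL, c("clean", "noisy", "forest_clean",
                                       "forest_noisy")))
  for (r in seq_len(n_runs)) {
    split_seed <- derive_seed(seed, 10 * r + 1)
    noise_seed <- derive_seed(seed, 10 * r + 2)
    fit_seed <- derive_seed(seed, 10 * r + 3)
    idx <- with_seed(split_seed, sample(l, n_train))
    xtr_c <- x[idx, , drop = FALSE]; xte_c <- x[-idx, , drop = FALSE]
    ytr <- y[idx]; yte <- y[-idx]
    xtr_n <- if (noise_on %in% c("both", "train")) {
      perturb(xtr_c, noise_seed)
    } else xtr_c
    xte_n <- if (noise_on %in% c("both", "test")) {
      perturb(xte_c, derive_seed(noise_seed, 1))
    } else xte_c
    for (cond in c("clean", "noisy")) {
      xtr <- if (cond == "clean") xtr_c else xtr_n
      xte <- if (cond == "clean") xte_c else xte_n
      fit <- ruleforest(xtr, ytr, seed = fit_seed, ...)
      r2[r, cond] <- r_squared(yte, predict(fit, xte))
      r2[r, paste0("forest_", cond)] <-
        r_squared(yte, predict(fit$forest, xte))
    }
  }

  paired_p <- function(a, b) {
    d <- a - b
    if (stats::sd(d) == 0) return(if (all(d == 0)) 1 else 0)
    stats::t.test(a, b, paired = TRUE)$p.value
  }
  structure(
    list(mean_r2_clean = mean(r2[, "clean"]),
         mean_r2_noisy = mean(r2[, "noisy"]),
         d_statistic = mean(r2[, "clean"]) - mean(r2[, "noisy"]),
         paired_t_p_value = paired_p(r2[, "clean"], r2[, "noisy"]),
         forest_mean_r2_clean = mean(r2[, "forest_clean"]),
         forest_mean_r2_noisy = mean(r2[, "forest_noisy"]),
         forest_d_statistic = mean(r2[, "forest_clean"]) -
           mean(r2[, "forest_noisy"]),
         forest_paired_t_p_value = paired_p(r2[, "forest_clean"],
                                            r2[, "forest_noisy"]),
         per_run_pairs = as.data.frame(r2),
         config = list(per_feature_probability = per_feature_probability,
                       noise_mean = noise_mean, noise_sd = noise_sd,
                       n_runs = n_runs, noise_on = noise_on, seed = seed)),
    class = "noise_report"
  )
}

#' @export
print.noise_report <- function(x, ...) {
  cat("Noise-robustness experiment (", x$config$n_runs, " runs)\n", sep = "")
  cat(sprintf("  rule model : R2 clean %.3f, noisy %.3f, D = %.3f (p = %.3g)\n",
              x$mean_r2_clean, x$mean_r2_noisy, x$d_statistic,
              x$paired_t_p_value))
  cat(sprintf("  forest     : R2 clean %.3f, noisy %.3f, D = %.3f (p = %.3g)\n",
              x$forest_mean_r2_clean, x$forest_mean_r2_noisy,
              x$forest_d_statistic, x$forest_paired_t_p_value))
  invisible(x)
}
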