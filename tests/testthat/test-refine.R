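# refinement configs kept small: the loop's behaviour, not the forest's
# accuracy, is under test here

test_that("an immediate fixed point takes exactly two iterations", {
  d <- make_artificial(n_per_class = 25, seed = 7)
  fit <- ruleforest(d, n_trees = 30, n_lambda = 5, n_folds = 3, seed = 7)
  # both features carry signal, so iteration 1 keeps them and iteration 2
  # confirms the set is stable
  expect_equal(fit$iterations, 2)
  expect_true(fit$converged)
  expect_equal(unname(fit$final_features), c(1, 2))
  expect_equal(nrow(fit$history), 2)
})

test_that("feature counts never increase and the loop terminates", {
  for (s in 1:3) {
    sim <- make_sparse_signal(n_samples = 150, n_features = 12,
                              n_informative = 2, seed = 70 + s)
    fit <- suppressWarnings(
      ruleforest(sim$data, n_trees = 25, min_samples_leaf = 30,
                 max_features = "all", n_lambda = 5, n_folds = 3, seed = s)
    )
    expect_lte(fit$iterations, fit$config$max_iterations)
    expect_true(all(diff(fit$history$n_features) <= 0))
    expect_equal(nrow(fit$history), fit$iterations)
  }
})

test_that("an empty selected feature set yields the constant model", {
  set.seed(81)
  x <- matrix(rnorm(80 * 4), 80, 4)
  y <- rnorm(80) # pure noise: the 1-SE rule should drop everything
  expect_warning(
    fit <- ruleforest(x, y, n_trees = 15, n_lambda = 5, n_folds = 3,
                      seed = 81),
    "empty"
  )
  expect_false(fit$converged)
  expect_length(fit$model$weights, 0)
  expect_equal(predict(fit, x), rep(fit$model$intercept, 80))
})

test_that("refinement is idempotent at its fixed point", {
  sim <- make_sparse_signal(n_samples = 150, n_features = 10,
                            n_informative = 2, seed = 91)
  fit <- suppressWarnings(
    ruleforest(sim$data, n_trees = 25, min_samples_leaf = 30,
               max_features = "all", n_lambda = 5, n_folds = 3,
               seed = 5, seed_policy = "fixed")
  )
  sel <- unname(fit$final_features)
  expect_gt(length(sel), 0)
  refit <- suppressWarnings(
    ruleforest(sim$data$x[, sel, drop = FALSE], sim$data$y, n_trees = 25,
               min_samples_leaf = 30, max_features = "all", n_lambda = 5,
               n_folds = 3, seed = 5, seed_policy = "fixed")
  )
  expect_equal(unname(sort(sel[refit$final_features])), sort(sel))
})

test_that("a single-pass fit records one iteration and skips convergence", {
  d <- make_artificial(n_per_class = 15, seed = 31)
  fit <- ruleforest(d, n_trees = 15, n_lambda = 4, n_folds = 3,
                    refine = FALSE, seed = 31)
  expect_equal(fit$iterations, 1)
  expect_true(is.na(fit$converged))
})

test_that("history round-trips through its CSV export", {
  d <- make_artificial(n_per_class = 15, seed = 41)
  fit <- ruleforest(d, n_trees = 15, n_lambda = 4, n_folds = 3, seed = 41)
  f <- tempfile(fileext = ".csv")
  write_history(fit, f)
  h <- read.csv(f)
  expect_equal(h$iteration, fit$history$iteration)
  expect_equal(h$n_rules, fit$history$n_rules)
  expect_equal(h$train_r2, fit$history$train_r2, tolerance = 1e-12)
})

test_that("fits are reproducible under a fixed master seed", {
  d <- make_artificial(n_per_class = 15, seed = 51)
  f1 <- ruleforest(d, n_trees = 12, n_lambda = 4, n_folds = 3, seed = 99)
  f2 <- ruleforest(d, n_trees = 12, n_lambda = 4, n_folds = 3, seed = 99)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$history, f2$history)
})
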