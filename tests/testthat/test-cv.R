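test_that("a one-point grid is chosen trivially", {
  inst <- random_lp_instance(l = 24, q = 10, seed = 51)
  sel <- select_lambda_cv(inst$X, inst$y, grid = 0.7, n_folds = 3,
                          fold_seed = 1)
  expect_equal(sel$chosen_lambda, 0.7)
  expect_equal(length(sel$cv_score), 1)
})

test_that("fold configuration is validated", {
  inst <- random_lp_instance(l = 10, q = 5, seed = 52)
  expect_error(select_lambda_cv(inst$X, inst$y, grid = 1, n_folds = 1),
               "n_folds")
  expect_error(select_lambda_cv(inst$X, inst$y, grid = 1, n_folds = 11),
               "n_folds")
  # 7 folds over 10 samples leaves folds with < 2 samples
  expect_error(select_lambda_cv(inst$X, inst$y, grid = 1, n_folds = 7),
               "at least 2 samples")
})

test_that("cross-validation is reproducible under a fixed fold seed", {
  inst <- random_lp_instance(l = 30, q = 12, seed = 53)
  g <- c(0.1, 1, 10)
  s1 <- select_lambda_cv(inst$X, inst$y, grid = g, n_folds = 3, fold_seed = 9)
  s2 <- select_lambda_cv(inst$X, inst$y, grid = g, n_folds = 3, fold_seed = 9)
  expect_identical(s1$cv_score, s2$cv_score)
  expect_identical(s1$fold_id, s2$fold_id)
})

test_that("pure-noise targets drive selection to the sparsest lambda", {
  # y carries no signal, so sparsity should win in most seeded repetitions
  wins_max <- 0L
  nz_frac <- numeric(20)
  for (r in 1:20) {
    set.seed(600 + r)
    X <- matrix(rnorm(40 * 25), 40, 25) * matrix(rbinom(40 * 25, 1, 0.3), 40)
    y <- rnorm(40)
    grid <- lambda_grid(X, y, n_lambda = 8)
    sel <- select_lambda_cv(X, y, grid = grid, n_folds = 4, fold_seed = r)
    if (sel$chosen_lambda == max(grid)) wins_max <- wins_max + 1L
    w <- solve_l1_lp(X, y, sel$chosen_lambda)$weights
    nz_frac[r] <- mean(w != 0)
  }
  expect_gte(wins_max, 10) # largest lambda chosen in >= 50% of repetitions
  expect_lt(mean(nz_frac), 0.05) # under 5% nonzero weights on noise
})

test_that("the 1-SE rule never chooses below the error-minimizing lambda", {
  inst <- random_lp_instance(l = 36, q = 15, seed = 55)
  grid <- lambda_grid(inst$X, inst$y, n_lambda = 7)
  s_min <- select_lambda_cv(inst$X, inst$y, grid = grid, n_folds = 3,
                            fold_seed = 2, rule = "min")
  s_1se <- select_lambda_cv(inst$X, inst$y, grid = grid, n_folds = 3,
                            fold_seed = 2, rule = "1se")
  expect_gte(s_1se$chosen_lambda, s_min$chosen_lambda)
  expect_equal(s_1se$lambda_min, s_min$chosen_lambda)
})
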