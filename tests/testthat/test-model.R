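test_that("pruning keeps exactly the rules above the zero tolerance", {
  rs <- artificial_rule_set()
  m_all <- prune_rules(rs, fake_solution(c(0.5, -2, 1, 0.3, -0.7, 2, 1.5)))
  expect_equal(length(m_all$weights), 7) # all weights above tolerance

  m_none <- prune_rules(rs, fake_solution(rep(0, 7), intercept = 4.2))
  expect_equal(length(m_none$weights), 0)
  expect_equal(predict(m_none, matrix(rnorm(10), 5, 2)), rep(4.2, 5))

  expect_error(prune_rules(rs, fake_solution(1:3)), "weights")
})

test_that("pruning zero-weight rules never changes predictions", {
  pl <- small_pipeline(seed = 12, n_per_class = 20, n_trees = 12)
  sel <- select_lambda_cv(pl$rm, pl$d$y, n_folds = 3, fold_seed = 3)
  sol <- solve_l1_lp(pl$rm, pl$d$y, sel$chosen_lambda)
  m <- prune_rules(pl$rs, sol, forest = pl$f)
  expect_gt(length(m$weights), 0)
  expect_lt(length(m$weights), length(pl$rs))
  set.seed(13)
  xs <- cbind(runif(100, 0, 5), runif(100, 0, 5))
  full_rm <- rule_matrix(xs, pl$rs, forest = pl$f)
  full_pred <- as.numeric(full_rm$values %*% sol$weights) + sol$intercept
  expect_lt(max(abs(predict(m, xs) - full_pred)), 1e-9)
})

test_that("prediction aligns named columns and tolerates extra ones", {
  d <- make_artificial(n_per_class = 15, seed = 14)
  fit <- ruleforest(d, n_trees = 12, n_lambda = 4, n_folds = 3, seed = 14)
  df <- as.data.frame(d) # includes the target column y
  expect_equal(predict(fit, df), predict(fit, d$x))
  # shuffled column order is aligned by name
  expect_equal(predict(fit, df[, c("y", "x2", "x1")]), predict(fit, d$x))
  expect_equal(predict(fit, df[, c("x2", "x1")]), predict(fit, d$x))
})

test_that("samples covered by no retained rule fall back to the intercept", {
  rs <- as_rule_set(list(rule(1, ">", 100, value = 9, tree = 1, leaf = 1)),
                    feature_names = c("x1", "x2"))
  m <- prune_rules(rs, fake_solution(2, intercept = 1.5))
  expect_equal(predict(m, matrix(c(1, 2, 3, 4), 2, 2)), c(1.5, 1.5))
})

test_that("features_in_rules collects the union of referenced features", {
  rs <- artificial_rule_set()
  m0 <- prune_rules(rs, fake_solution(rep(0, 7)))
  expect_length(features_in_rules(m0), 0)

  m <- prune_rules(rs, fake_solution(rep(1, 7)))
  expect_equal(unname(features_in_rules(m)), c(1, 2))
  expect_equal(names(features_in_rules(m)), c("x1", "x2"))

  mb <- prune_rules(breast_rule_set(), fake_solution(rep(1, 5)))
  expect_length(features_in_rules(mb), 20) # 20 distinct variables
})

test_that("top rules are ordered by weight magnitude with stable ties", {
  rs <- artificial_rule_set()[1:3]
  m <- prune_rules(rs, fake_solution(c(0.5, -2, 1)))
  tr <- top_rules(m, 2)
  expect_equal(tr$weights, c(-2, 1))
  expect_equal(tr$rules$info$tree, c(2, 3))
  # k beyond the rule count returns everything
  expect_length(top_rules(m, 50)$weights, 3)
  # exact ties fall back to tree then leaf order
  m2 <- prune_rules(rs, fake_solution(c(1, -1, 1)))
  expect_equal(top_rules(m2, 3)$rules$info$tree, c(1, 2, 3))
})

test_that("interpretability statistics match hand counts", {
  rs <- artificial_rule_set()
  m0 <- prune_rules(rs, fake_solution(rep(0, 7)))
  st0 <- interpretability_stats(m0)
  expect_equal(st0$n_rules, 0)
  expect_equal(st0$mean_conditions_per_rule, 0)
  expect_equal(st0$n_features_selected, 0)

  st <- interpretability_stats(prune_rules(rs, fake_solution(rep(1, 7))))
  expect_equal(st$n_rules, 7)

  stb <- interpretability_stats(
    prune_rules(breast_rule_set(), fake_solution(rep(1, 5))))
  expect_equal(stb$n_rules, 5)
  expect_equal(stb$mean_conditions_per_rule, mean(c(8, 5, 2, 6, 4)))
  expect_equal(stb$sd_conditions_per_rule, sd(c(8, 5, 2, 6, 4)))
  expect_equal(stb$n_features_selected, 20)
})
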