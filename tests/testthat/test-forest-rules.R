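test_that("constant targets give trees whose every leaf predicts the constant", {
  x <- matrix(rnorm(60), 30, 2)
  # randomForest itself warns about the degenerate (constant) response
  f <- suppressWarnings(fit_forest(x, rep(3.5, 30), n_trees = 12, seed = 1))
  rs <- extract_rules(f)
  expect_equal(length(rs), n_leaves(f)) # one rule per leaf
  expect_true(all(rs$info$value == 3.5))
  expect_equal(predict(f, x), rep(3.5, 30))
  # single-node trees yield rules with an empty (vacuous) conjunction
  single <- which(tabulate(rs$info$tree, 12) == 1)
  expect_gt(length(single), 0)
  r <- rs[[which(rs$info$tree == single[1])[1]]]
  expect_equal(nrow(r$conditions), 0)
  expect_true(rule_covers(r, c(0, 0))) # vacuous conjunction
})

test_that("forests and their rule sets are reproducible under a fixed seed", {
  d <- make_artificial(n_per_class = 15, seed = 3)
  f1 <- fit_forest(d, n_trees = 10, seed = 11)
  f2 <- fit_forest(d, n_trees = 10, seed = 11)
  expect_identical(extract_rules(f1)[c("conditions", "info")],
                   extract_rules(f2)[c("conditions", "info")])
})

test_that("invalid forest configuration is rejected", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(fit_forest(x, rnorm(5), min_samples_leaf = 10),
               "min_samples_leaf")
  expect_error(fit_forest(x, rnorm(5), n_trees = 0), "n_trees")
  expect_error(fit_forest(x, rnorm(5), max_features = 2), "max_features")
})

test_that("extracted conditions form one interval per feature", {
  pl <- small_pipeline(seed = 5, n_per_class = 30, n_trees = 20)
  cn <- pl$rs$conditions
  # at most one "<=" and one ">" per (rule, feature)
  key <- paste(cn$rule, cn$feature, cn$op)
  expect_false(any(duplicated(key)))
  # where both bounds exist, lower < upper for every satisfiable rule;
  # bagged trees occasionally carry an unreachable branch whose interval is
  # empty, and exactly those rules must cover nothing
  wide <- merge(cn[cn$op == ">", c("rule", "feature", "threshold")],
                cn[cn$op == "<=", c("rule", "feature", "threshold")],
                by = c("rule", "feature"), suffixes = c("_lo", "_hi"))
  empty_iv <- unique(wide$rule[wide$threshold_lo >= wide$threshold_hi])
  set.seed(1)
  xs <- cbind(runif(500, -3, 8), runif(500, -3, 8))
  cover <- rule_matrix(xs, pl$rs)$coverage
  if (length(empty_iv)) {
    expect_equal(sum(cover[, empty_iv]), 0)
  }
  live <- setdiff(seq_len(length(pl$rs)), empty_iv)
  expect_gt(length(live), 0.9 * length(pl$rs))
})

test_that("rule conjunction membership matches the printed example", {
  r <- rule(c(2, 1), c("<=", ">"), c(2.04, 3.84), value = 5)
  expect_true(rule_covers(r, c(4.0, 1.0)))
  expect_false(rule_covers(r, c(3.0, 1.0))) # violates x1 > 3.84
  expect_error(rule_covers(r, 1.0), "feature")
})

test_that("rules of one tree partition the feature space", {
  pl <- small_pipeline(seed = 8, n_per_class = 25, n_trees = 10)
  set.seed(99)
  xs <- cbind(runif(1000, -2, 7), runif(1000, -2, 7))
  rm <- rule_matrix(xs, pl$rs) # condition-based path
  cover <- rm$coverage
  for (k in unique(pl$rs$info$tree)) {
    cols <- which(pl$rs$info$tree == k)
    hits <- Matrix::rowSums(cover[, cols, drop = FALSE])
    expect_true(all(hits == 1)) # exactly one rule per tree covers any point
  }
})

test_that("rule-space encoding reconstructs the forest's predictions", {
  pl <- small_pipeline(seed = 2, n_per_class = 25, n_trees = 20)
  # every row covered once per tree
  expect_true(all(Matrix::rowSums(pl$rm$coverage) == 20))
  # uniform weights 1/T and b = 0 reproduce the ensemble predictions
  recon <- as.numeric(pl$rm$values %*% rep(1 / 20, pl$rm$q))
  expect_lt(max(abs(recon - predict(pl$f, pl$d))), 1e-9)
  # fresh samples, both encoding paths
  set.seed(7)
  xs <- cbind(runif(50, 0, 5), runif(50, 0, 5))
  rm_fast <- rule_matrix(xs, pl$rs, forest = pl$f)
  rm_slow <- rule_matrix(xs, pl$rs)
  expect_identical(as.matrix(rm_fast$values), as.matrix(rm_slow$values))
  expect_lt(max(abs(as.numeric(rm_fast$values %*% rep(1 / 20, pl$rm$q)) -
                      predict(pl$f, xs))), 1e-9)
})

test_that("stump forests encode as a constant column", {
  x <- matrix(rnorm(40), 20, 2)
  f <- suppressWarnings(fit_forest(x, rep(2.5, 20), n_trees = 1, seed = 4))
  rs <- extract_rules(f)
  rm <- rule_matrix(x, rs, forest = f)
  expect_equal(dim(rm$values), c(20, 1))
  expect_true(all(as.matrix(rm$values) == 2.5))
})

test_that("a pruned rule set leaves uncovered rows at zero", {
  rs <- as_rule_set(list(
    rule(1, ">", 100, value = 9, tree = 1, leaf = 1)
  ), feature_names = c("x1", "x2"))
  rm <- rule_matrix(matrix(c(1, 2, 3, 4), 2, 2), rs)
  expect_equal(sum(rm$coverage), 0)
  expect_true(all(as.matrix(rm$values) == 0))
})

test_that("coverage is tracked by membership even for zero-valued leaves", {
  rs <- as_rule_set(list(rule(1, "<=", 10, value = 0, tree = 1, leaf = 1)),
                    feature_names = "x1")
  rm <- rule_matrix(matrix(c(1, 2), 2, 1), rs)
  expect_equal(sum(rm$coverage), 2) # covered although the value is 0
  expect_true(all(as.matrix(rm$values) == 0))
})

test_that("rule text renders in the IF-THEN style", {
  rs <- artificial_rule_set()
  expect_equal(format_rules(rs[1]),
               "IF x2 <= 2.04 AND x1 > 3.84 THEN y = 5.00")
  expect_equal(format_rules(rs[4]),
               "IF x1 <= 3.68 AND x2 <= 1.93 AND x1 > 2.09 THEN y = 4.00")
  stump <- as_rule_set(list(rule(value = 3.5, tree = 1, leaf = 1)), "x1")
  expect_equal(format_rules(stump), "IF TRUE THEN y = 3.50")
})

test_that("feature occurrence counts rules, not conditions", {
  expect_identical(feature_occurrence(list()), integer(0))
  counts <- feature_occurrence(artificial_rule_set())
  expect_equal(unname(counts), c(6, 7)) # x1 in 6 rules, x2 in all 7
  # an interval on one feature contributes a single count
  iv <- as_rule_set(list(
    rule(c(1, 1), c("<=", ">"), c(3.68, 2.09), value = 4, tree = 1, leaf = 1)
  ), feature_names = c("x1", "x2"))
  expect_equal(unname(feature_occurrence(iv)), c(1, 0))
})
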