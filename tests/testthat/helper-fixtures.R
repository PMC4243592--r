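# Shared fixtures built in code.

# The seven artificial-data rules printed as the worked example
# (features: 1 = x1, 2 = x2).
artificial_rules <- function() {
  list(
    rule(c(2, 1), c("<=", ">"), c(2.04, 3.84), value = 5, tree = 1, leaf = 1),
    rule(c(2, 1), c("<=", ">"), c(1.21, 3.75), value = 5, tree = 2, leaf = 1),
    rule(c(2, 2), c("<=", ">"), c(4.17, 3.91), value = 6, tree = 3, leaf = 1),
    rule(c(1, 2, 1), c("<=", "<=", ">"), c(3.68, 1.93, 2.09), value = 4,
         tree = 4, leaf = 1),
    rule(c(2, 1), c(">", "<="), c(4.21, 2.62), value = 6, tree = 5, leaf = 1),
    rule(c(2, 2, 1), c("<=", ">", ">"), c(2.33, 0.93, 3.66), value = 5,
         tree = 6, leaf = 1),
    rule(c(2, 1), c(">", "<="), c(3.88, 2.72), value = 6, tree = 7, leaf = 1)
  )
}

artificial_rule_set <- function() {
  as_rule_set(artificial_rules(), feature_names = c("x1", "x2"))
}

# The five breast-cancer rules printed as a worked example; conjunct counts
# are (8, 5, 2, 6, 4) and the rules reference 20 distinct variables.
breast_rule_set <- function() {
  rules <- list(
    rule(c(22, 1, 5, 11, 25, 14, 20, 20),
         c(">", "<=", ">", ">", "<=", ">", ">", "<="),
         c(30.27, 17.23, 0.09, 0.24, 0.16, 28.38, 0.00, 0.01),
         value = 64.5, tree = 1, leaf = 1),
    rule(c(12, 9, 3, 16, 21),
         c("<=", "<=", ">", ">", ">"),
         c(1.17, 0.18, 88.13, 0.02, 23.37),
         value = 57, tree = 2, leaf = 1),
    rule(c(4, 12), c(">", "<="), c(814.40, 0.70),
         value = 101.33, tree = 3, leaf = 1),
    rule(c(17, 30, 19, 31, 16, 23),
         c("<=", "<=", "<=", ">", "<=", "<="),
         c(0.05, 0.10, 0.01, 0.70, 0.03, 130.75),
         value = 69.25, tree = 4, leaf = 1),
    rule(c(23, 29, 2, 17), c(">", ">", "<=", ">"),
         c(123.70, 0.26, 18.43, 0.03),
         value = 109.2, tree = 5, leaf = 1)
  )
  as_rule_set(rules, feature_names = paste0("v", 1:31))
}

# wrap a raw weight vector as an lp_solution so prune_rules can consume it
fake_solution <- function(weights, intercept = 0, lambda = 1) {
  structure(
    list(weights = weights, intercept = intercept,
         slacks = numeric(0), objective_value = NA_real_, lambda = lambda,
         solver_status = "optimal", dual = NULL, iterations = 0L),
    class = "lp_solution"
  )
}

# small forest + rules + matrix used across tests
small_pipeline <- function(seed = 42, n_per_class = 20, n_trees = 15) {
  d <- make_artificial(n_per_class = n_per_class, seed = seed)
  f <- fit_forest(d, n_trees = n_trees, seed = seed + 1)
  rs <- extract_rules(f)
  rm <- rule_matrix(d, rs, forest = f)
  list(d = d, f = f, rs = rs, rm = rm)
}

random_lp_instance <- function(l, q, seed, density = 0.6) {
  set.seed(seed)
  X <- matrix(stats::rnorm(l * q), l, q) *
    matrix(stats::rbinom(l * q, 1, density), l, q)
  list(X = X, y = stats::rnorm(l, 0, 2))
}
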