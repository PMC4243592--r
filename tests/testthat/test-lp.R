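test_that("huge lambda reduces the LP to the L1 location problem", {
  y <- c(1, 2, 3, 7)
  X <- matrix(c(1, 0, 0, 1, 0, 1, 1, 0), 4, 2)
  s <- solve_l1_lp(X, y, lambda = 1e9)
  expect_equal(s$solver_status, "optimal")
  expect_true(all(s$weights == 0))
  # any median of y minimizes the sum of absolute deviations
  expect_equal(s$objective_value, sum(abs(y - median(y))))
  expect_gte(s$intercept, 2)
  expect_lte(s$intercept, 3)
})

test_that("an interpolable system reaches zero slack as lambda -> 0", {
  y <- c(1, 2, 3, 7)
  X <- diag(c(2, 3, 1, 5))
  s <- solve_l1_lp(X, y, lambda = 1e-8)
  expect_lt(max(s$slacks), 1e-6)
})

test_that("the interior-point solver matches the simplex oracle", {
  # a handful here; the full 20-instance sweep runs in the acceptance suite
  for (k in 1:6) {
    inst <- random_lp_instance(l = 15 + k, q = 10 + k, seed = 300 + k)
    lam <- 10^runif(1, -1.5, 0.5)
    o <- oracle_l1lp(inst$X, inst$y, lam)
    s <- solve_l1_lp(inst$X, inst$y, lam)
    expect_equal(s$objective_value, o$objective,
                 tolerance = 1e-6)
  }
})

test_that("solutions are feasible and beat the intercept-only point", {
  inst <- random_lp_instance(l = 25, q = 20, seed = 17)
  base <- sum(abs(inst$y - median(inst$y)))
  for (lam in c(0.01, 0.3, 2, 50)) {
    s <- solve_l1_lp(inst$X, inst$y, lam)
    expect_equal(s$solver_status, "optimal")
    # slack constraints hold exactly by construction of the returned slacks
    resid <- abs(as.numeric(inst$X %*% s$weights) + s$intercept - inst$y)
    expect_true(all(resid <= s$slacks + 1e-9))
    # optimality certificate: no worse than the feasible (0, median) point
    expect_lte(s$objective_value, base * (1 + 1e-8))
  }
})

test_that("the L1 norm of the solution shrinks along an increasing grid", {
  inst <- random_lp_instance(l = 30, q = 25, seed = 23)
  grid <- 10^seq(-2, 2, length.out = 9)
  norms <- vapply(grid, function(lam) {
    sum(abs(solve_l1_lp(inst$X, inst$y, lam)$weights))
  }, 1)
  expect_true(all(diff(norms) <= 1e-6))
})

test_that("identically zero columns get weight exactly zero", {
  inst <- random_lp_instance(l = 20, q = 8, seed = 31)
  X <- cbind(inst$X[, 1:4], 0, inst$X[, 5:8], 0)
  s <- solve_l1_lp(X, inst$y, lambda = 0.5)
  expect_identical(s$weights[c(5, 10)], c(0, 0))
  s2 <- solve_l1_lp(inst$X, inst$y, lambda = 0.5)
  expect_equal(s$objective_value, s2$objective_value, tolerance = 1e-8)
})

test_that("column generation agrees with the direct solve", {
  set.seed(41)
  l <- 60
  q <- 2500 # above the column-generation threshold
  X <- Matrix::rsparsematrix(l, q, density = 0.05,
                             rand.x = function(n) rnorm(n, 2, 1))
  y <- rnorm(l, 3, 2)
  lam <- 0.5
  direct <- ruleforest:::l1lp_core(X, y, lam)
  s <- solve_l1_lp(X, y, lam)
  expect_equal(s$objective_value, direct$objective, tolerance = 1e-6)
})

test_that("bad inputs are rejected", {
  X <- matrix(1:6, 3, 2)
  expect_error(solve_l1_lp(X, 1:2, 1), "rows")
  expect_error(solve_l1_lp(X, 1:3, -1), "positive")
  expect_error(solve_l1_lp(X, 1:3, c(1, 2)), "single")
})
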