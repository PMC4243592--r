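# L1-regularized rule-weight linear program
#
#   min_{w, b, xi}  lambda * ||w||_1 + sum_i xi_i
#   s.t.            |w' X_i + b - y_i| <= xi_i,   xi_i >= 0
#
# Solved as a primal-dual interior-point method (Mehrotra predictor-
# corrector) on the equivalent standard form obtained from the split
# w = u - v (u, v >= 0) and xi = (s1 + s2)/2 with s1 = xi - r, s2 = xi + r
# for the residual r = Xw + b - y:
#
#   min lambda 1'(u + v) + (1/2) 1'(s1 + s2)
#   s.t. X(u - v) + 1 b + (s1 - s2)/2 = y,  u, v, s1, s2 >= 0, b free.
#
# The free intercept contributes one dense row/column to the KKT system and
# is handled by block elimination, so each iteration factorizes only the
# l x l normal matrix X W X' + D. For large rule matrices an outer column-
# generation loop solves on a working subset of columns and certifies the
# full dual feasibility |X_j' p| <= lambda before terminating.

l1lp_core <- function(X, y, lambda, tol = 1e-8, maxit = 100) {
  X <- methods::as(X, "CsparseMatrix")
  l <- nrow(X)
  q <- ncol(X)
  Xt <- Matrix::t(X)
  # feasible, well-centred starting point
  b0 <- stats::median(y)
  r0 <- y - b0
  t0 <- max(1, mean(abs(r0)))
  u <- rep(0.1, q); v <- rep(0.1, q)
  s1 <- pmax(r0, 0) + t0; s2 <- pmax(-r0, 0) + t0
  bb <- b0; p <- rep(0, l)
  du <- rep(lambda, q); dv <- rep(lambda, q)
  ds1 <- rep(0.5, l); ds2 <- rep(0.5, l)
  n <- 2 * q + 2 * l
  one <- rep(1, l)
  ynorm <- 1 + sqrt(sum(y^2))
  cnorm <- 1 + lambda * sqrt(max(q, 1))
  best <- NULL
  best_err <- Inf
  status <- "numerical-failure"
  iter <- 0L
  xidx <- rep.int(seq_len(q), diff(X@p)) # column index of each nonzero

  for (it in seq_len(maxit)) {
    iter <- it
    Xp <- as.numeric(Xt %*% p)
    rb <- as.numeric(X %*% (u - v)) + bb + 0.5 * (s1 - s2) - y
    rcu <- Xp + du - lambda
    rcv <- -Xp + dv - lambda
    rcs1 <- 0.5 * p + ds1 - 0.5
    rcs2 <- -0.5 * p + ds2 - 0.5
    rcb <- sum(p)
    mu <- (sum(u * du) + sum(v * dv) + sum(s1 * ds1) + sum(s2 * ds2)) / n
    pobj <- lambda * (sum(u) + sum(v)) + 0.5 * (sum(s1) + sum(s2))
    dobj <- sum(y * p)
    gap <- abs(pobj - dobj) / (1 + abs(pobj))
    pinf <- sqrt(sum(rb^2)) / ynorm
    dinf <- sqrt(sum(rcu^2) + sum(rcv^2) + sum(rcs1^2) + sum(rcs2^2) +
                   rcb^2) / cnorm
    err <- max(gap, pinf, dinf)
    if (err < best_err) {
      best_err <- err
      best <- list(w = u - v, b = bb, p = p, obj = pobj)
    }
    if (err < tol) {
      status <- "optimal"
      break
    }
    if (mu < 1e-16 * (1 + abs(pobj))) break # complementarity exhausted

    Wu <- u / du; Wv <- v / dv; Ws1 <- s1 / ds1; Ws2 <- s2 / ds2
    Xs <- X
    Xs@x <- X@x * sqrt(Wu + Wv)[xidx]
    M <- as.matrix(Matrix::tcrossprod(Xs))
    diag(M) <- diag(M) + 0.25 * (Ws1 + Ws2) + 1e-12 * max(diag(M), 1)
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) {
      diag(M) <- diag(M) * (1 + 1e-8) + 1e-8
      R <- tryCatch(chol(M), error = function(e) NULL)
      if (is.null(R)) break
    }
    solveM <- function(rhs) backsolve(R, backsolve(R, rhs, transpose = TRUE))
    g <- solveM(one)
    sg <- sum(g)
    newton <- function(xu, xv, xs1, xs2) {
      h1 <- as.numeric(X %*% (-xu / du + Wu * rcu + xv / dv - Wv * rcv)) +
        0.5 * (-xs1 / ds1 + Ws1 * rcs1 + xs2 / ds2 - Ws2 * rcs2)
      a <- solveM(-rb - h1)
      db <- (sum(a) + rcb) / sg
      dp <- a - g * db
      Xdp <- as.numeric(Xt %*% dp)
      ddu <- -rcu - Xdp; ddv <- -rcv + Xdp
      dds1 <- -rcs1 - 0.5 * dp; dds2 <- -rcs2 + 0.5 * dp
      list(du = -(xu + u * ddu) / du, dv = -(xv + v * ddv) / dv,
           ds1 = -(xs1 + s1 * dds1) / ds1, ds2 = -(xs2 + s2 * dds2) / ds2,
           db = db, dp = dp,
           ddu = ddu, ddv = ddv, dds1 = dds1, dds2 = dds2)
    }
    maxstep <- function(z, dz) {
      neg <- dz < 0
      if (!any(neg)) Inf else min(-z[neg] / dz[neg])
    }
    aff <- newton(u * du, v * dv, s1 * ds1, s2 * ds2)
    ap <- min(1, maxstep(u, aff$du), maxstep(v, aff$dv),
              maxstep(s1, aff$ds1), maxstep(s2, aff$ds2))
    ad <- min(1, maxstep(du, aff$ddu), maxstep(dv, aff$ddv),
              maxstep(ds1, aff$dds1), maxstep(ds2, aff$dds2))
    mu_aff <- (sum((u + ap * aff$du) * (du + ad * aff$ddu)) +
                 sum((v + ap * aff$dv) * (dv + ad * aff$ddv)) +
                 sum((s1 + ap * aff$ds1) * (ds1 + ad * aff$dds1)) +
                 sum((s2 + ap * aff$ds2) * (ds2 + ad * aff$dds2))) / n
    sig <- max(1e-8, min(1, mu_aff / mu))^3
    dir <- newton(u * du + aff$du * aff$ddu - sig * mu,
                  v * dv + aff$dv * aff$ddv - sig * mu,
                  s1 * ds1 + aff$ds1 * aff$dds1 - sig * mu,
                  s2 * ds2 + aff$ds2 * aff$dds2 - sig * mu)
    ap <- 0.9995 * min(1 / 0.9995, maxstep(u, dir$du), maxstep(v, dir$dv),
                       maxstep(s1, dir$ds1), maxstep(s2, dir$ds2))
    ad <- 0.9995 * min(1 / 0.9995, maxstep(du, dir$ddu), maxstep(dv, dir$ddv),
                       maxstep(ds1, dir$dds1), maxstep(ds2, dir$dds2))
    u <- u + ap * dir$du; v <- v + ap * dir$dv
    s1 <- s1 + ap * dir$ds1; s2 <- s2 + ap * dir$ds2
    bb <- bb + ap * dir$db
    p <- p + ad * dir$dp
    du <- du + ad * dir$ddu; dv <- dv + ad * dir$ddv
    ds1 <- ds1 + ad * dir$dds1; ds2 <- ds2 + ad * dir$dds2
  }
  if (status != "optimal" && best_err < 100 * tol) status <- "optimal"
  list(w = best$w, b = best$b, dual = best$p, objective = best$obj,
       status = status, iterations = iter, accuracy = best_err)
}

#' Solve the 1-norm-regularized rule-weight linear program
#'
#' Minimizes `lambda * ||w||_1 + sum(xi)` subject to
#' `|w' X_i + b - y_i| <= xi_i` over rule weights `w`, an unpenalized free
#' intercept `b`, and per-sample slack variables `xi`. Solved by a
#' primal-dual interior-point method specialized to this structure; for wide
#' rule matrices a column-generation outer loop works on an active subset of
#' columns and terminates only once dual feasibility `|X_j' p| <= lambda` is
#' certified for every column. Columns that are identically zero on the
#' training samples are dropped (their weight is fixed at 0).
#'
#' After convergence the solution is polished: the LP is re-solved on the
#' support of `w`, weights off the support are set exactly to zero, and the
#' polished solution is kept only if its objective matches. This yields a
#' vertex-like sparse solution so that pruning zero-weight rules is exactly
#' prediction-invariant.
#'
#' @param rule_matrix a [rule_matrix()] object, numeric matrix, or sparse
#'   Matrix with samples in rows and rules in columns.
#' @param targets numeric response vector.
#' @param lambda positive regularization parameter.
#' @param tol relative convergence tolerance on duality gap and feasibility.
#' @param maxit maximum interior-point iterations per solve.
#' @param polish logical; re-solve on the support to sharpen sparsity.
#' @param work_init optional integer vector of column indices used to seed
#'   the column-generation working set (e.g. the active set of a
#'   neighbouring `lambda` on a regularization path); correctness does not
#'   depend on it.
#' @return An object of class `"lp_solution"`: `weights` (length q),
#'   `intercept`, `slacks`, `objective_value`, `lambda`, `solver_status`
#'   (`"optimal"` or `"numerical-failure"`), `dual`, `iterations`.
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' y <- rnorm(10)
#' s <- solve_l1_lp(X, y, lambda = 0.5)
#' s$objective_value
#' @export
solve_l1_lp <- function(rule_matrix, targets, lambda, tol = 1e-8,
                        maxit = 100, polish = TRUE, work_init = NULL) {
  X <- rm_values(rule_matrix)
  y <- as.numeric(targets)
  if (nrow(X) != length(y)) {
    stop2("rule matrix has ", nrow(X), " rows but targets has length ",
          length(y))
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop2("`lambda` must be a single positive number")
  }
  q <- ncol(X)
  nzcol <- which(diff(X@p) > 0L)
  Xnz <- X[, nzcol, drop = FALSE]
  qnz <- length(nzcol)

  if (qnz == 0L) {
    # no usable columns: the LP reduces to the L1 location problem in b
    b <- stats::median(y)
    xi <- abs(y - b)
    return(structure(
      list(weights = numeric(q), intercept = b, slacks = xi,
           objective_value = sum(xi), lambda = lambda,
           solver_status = "optimal", dual = sign(y - b), iterations = 0L),
      class = "lp_solution"
    ))
  }

  # analytic shortcut: w = 0, b = median(y) is optimal whenever a dual
  # certificate theta (|theta| <= 1, 1'theta = 0, |X_j' theta| <= lambda)
  # attains the intercept-only objective; exact, so large-lambda grid
  # points cost nothing
  b0 <- stats::median(y)
  theta <- sign(y - b0)
  imb <- sum(theta)
  zero_at <- which(theta == 0)
  if (abs(imb) <= length(zero_at)) {
    if (length(zero_at)) theta[zero_at] <- -imb / length(zero_at)
    if (max(abs(as.numeric(Matrix::crossprod(Xnz, theta)))) <=
        lambda * (1 + 1e-12)) {
      xi <- abs(y - b0)
      return(structure(
        list(weights = numeric(q), intercept = b0, slacks = xi,
             objective_value = sum(xi), lambda = lambda,
             solver_status = "optimal", dual = theta, iterations = 0L),
        class = "lp_solution"
      ))
    }
  }

  colgen_limit <- max(3000L, 8L * nrow(X))
  if (qnz <= colgen_limit) {
    sol <- l1lp_core(Xnz, y, lambda, tol, maxit)
    work <- seq_len(qnz)
  } else {
    # column generation: start from the columns most correlated with the
    # sign pattern of the intercept-only residual
    s0 <- sign(y - stats::median(y))
    score <- abs(as.numeric(Matrix::crossprod(Xnz, s0)))
    work <- order(score, decreasing = TRUE)[seq_len(colgen_limit)]
    if (!is.null(work_init)) {
      wi <- match(intersect(work_init, nzcol), nzcol)
      work <- unique(c(wi, work))
    }
    sol <- NULL
    for (round in 1:40) {
      sol <- l1lp_core(Xnz[, work, drop = FALSE], y, lambda, tol, maxit)
      viol <- abs(as.numeric(Matrix::crossprod(Xnz, sol$dual))) - lambda
      viol[work] <- -Inf
      bad <- which(viol > max(1e-7 * lambda, 1e-9))
      if (length(bad) == 0L) break
      bad <- bad[order(viol[bad], decreasing = TRUE)]
      work <- c(work, utils::head(bad, 1500L))
    }
  }

  w_nz <- numeric(qnz)
  w_nz[work] <- sol$w
  b <- sol$b
  status <- sol$status

  if (polish && status == "optimal") {
    ref_obj <- lambda * sum(abs(w_nz)) + sum(abs(as.numeric(Xnz %*% w_nz) + b - y))
    for (round in 1:4) {
      supp <- which(abs(w_nz) > 1e-6 * max(1, max(abs(w_nz))))
      if (length(supp) == qnz) break
      if (length(supp) == 0L) {
        bm <- stats::median(y)
        if (sum(abs(y - bm)) <= ref_obj + 1e-7 * (1 + abs(ref_obj))) {
          w_nz <- numeric(qnz)
          b <- bm
        }
        break
      }
      ps <- l1lp_core(Xnz[, supp, drop = FALSE], y, lambda, tol, maxit)
      if (ps$status != "optimal") break
      w_try <- numeric(qnz)
      w_try[supp] <- ps$w
      obj_try <- lambda * sum(abs(w_try)) +
        sum(abs(as.numeric(Xnz %*% w_try) + ps$b - y))
      if (obj_try <= ref_obj + 1e-7 * (1 + abs(ref_obj))) {
        w_new_supp <- which(abs(w_try) > 1e-6 * max(1, max(abs(w_try))))
        stable <- length(w_new_supp) == length(supp)
        w_nz <- w_try
        b <- ps$b
        if (stable) break
      } else {
        break
      }
    }
  }

  w <- numeric(q)
  w[nzcol] <- w_nz
  resid <- as.numeric(X %*% w) + b - y
  xi <- abs(resid)
  out <- structure(
    list(weights = w, intercept = b, slacks = xi,
         objective_value = lambda * sum(abs(w)) + sum(xi),
         lambda = lambda, solver_status = status,
         dual = sol$dual, iterations = sol$iterations),
    class = "lp_solution"
  )
  attr(out, "work") <- nzcol[work]
  out
}

#' @export
print.lp_solution <- function(x, ...) {
  cat("<lp_solution> lambda = ", format(x$lambda), ", status = ",
      x$solver_status, "\n  nonzero weights: ",
      sum(x$weights != 0), " / ", length(x$weights),
      ", objective = ", format(x$objective_value), "\n", sep = "")
  invisible(x)
}
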