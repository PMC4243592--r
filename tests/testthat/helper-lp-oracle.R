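# Independent LP oracle: dense two-phase simplex (Bland's rule) on the
# explicit constraint matrix of the rule-weight program, coded separately
# from the package's interior-point solver.
#
#   min c'z  s.t.  A z = b, z >= 0
simplex_solve <- function(A, b, cost, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  # phase 1: artificial variables
  Tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  obj <- c(rep(0, n), rep(1, m))
  run_simplex <- function(Tab, basis, obj) {
    repeat {
      nb <- setdiff(seq_len(ncol(Tab) - 1L), basis)
      cb <- obj[basis]
      red <- obj[nb] - as.numeric(crossprod(cb, Tab[, nb, drop = FALSE]))
      ent <- nb[which(red < -tol)]
      if (length(ent) == 0L) return(list(Tab = Tab, basis = basis))
      j <- min(ent) # Bland's rule
      col <- Tab[, j]
      pos <- which(col > tol)
      if (length(pos) == 0L) stop("unbounded LP")
      ratios <- Tab[pos, ncol(Tab)] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + tol]
      i <- cand[which.min(basis[cand])]
      piv <- Tab[i, j]
      Tab[i, ] <- Tab[i, ] / piv
      for (r in seq_len(nrow(Tab))) {
        if (r != i && abs(Tab[r, j]) > 0) Tab[r, ] <- Tab[r, ] - Tab[r, j] * Tab[i, ]
      }
      basis[i] <- j
    }
  }
  # reduce phase-1 objective rows: use simplex with obj on x and artificials
  res <- run_simplex(Tab, basis, obj)
  p1 <- sum(obj[res$basis] * res$Tab[, ncol(res$Tab)])
  if (p1 > 1e-7) stop("infeasible LP (phase 1 residual ", p1, ")")
  Tab <- res$Tab; basis <- res$basis
  # drive remaining artificial variables out of the basis where possible
  for (i in which(basis > n)) {
    row <- Tab[i, seq_len(n)]
    j <- which(abs(row) > tol)[1]
    if (!is.na(j)) {
      piv <- Tab[i, j]
      Tab[i, ] <- Tab[i, ] / piv
      for (r in seq_len(nrow(Tab))) {
        if (r != i && abs(Tab[r, j]) > 0) Tab[r, ] <- Tab[r, ] - Tab[r, j] * Tab[i, ]
      }
      basis[i] <- j
    }
  }
  # phase 2 on original columns only (artificial columns frozen at zero)
  keep <- c(seq_len(n), ncol(Tab))
  live <- basis <= n
  Tab2 <- Tab[live, keep, drop = FALSE]
  basis2 <- basis[live]
  res2 <- run_simplex(Tab2, basis2, c(cost, 0))
  z <- numeric(n)
  z[res2$basis] <- res2$Tab[, ncol(res2$Tab)]
  list(z = z, objective = sum(cost * z))
}

# Explicit standard form of:  min lambda ||w||_1 + sum xi
#   s.t. |X w + b - y| <= xi
# variables z = (u q, v q, bp, bm, xi l, s_upper l, s_lower l)
oracle_l1lp <- function(X, y, lambda) {
  X <- as.matrix(X)
  l <- nrow(X); q <- ncol(X)
  Il <- diag(l)
  # Xw + b - y <= xi   ->  Xu - Xv + bp - bm - xi + s_up = y
  # -(Xw + b - y) <= xi -> -Xu + Xv - bp + bm - xi + s_lo = -y
  A <- rbind(
    cbind(X, -X, 1, -1, -Il, Il, matrix(0, l, l)),
    cbind(-X, X, -1, 1, -Il, matrix(0, l, l), Il)
  )
  b <- c(y, -y)
  cost <- c(rep(lambda, 2 * q), 0, 0, rep(1, l), rep(0, 2 * l))
  sol <- simplex_solve(A, b, cost)
  w <- sol$z[seq_len(q)] - sol$z[q + seq_len(q)]
  list(objective = sol$objective, w = w,
       b = sol$z[2 * q + 1] - sol$z[2 * q + 2],
       xi = sol$z[2 * q + 2 + seq_len(l)])
}
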