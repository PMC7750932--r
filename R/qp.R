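# Exact solver for the weight-update quadratic program:
#
#   minimize   sum_m  theta_m' Q_m theta_m
#   subject to sum_m theta_im = 1 and theta_im >= 0 for every observation i
#              (the sum running over the datasets in which i is observed),
#              theta_im = 0 where observation i is missing from dataset m.
#
# The Hessian is block diagonal over datasets (blocks 2 Q_m) while the
# constraints couple only within a row of Theta, so cyclic block-coordinate
# descent over rows is exact: each row subproblem is a separable quadratic
# over a simplex, solved in closed form by waterfilling. With the ridge the
# per-row subproblems are strictly convex, the objective decreases
# monotonically, and the iterates converge to the global optimum of the
# (convex) QP.

# Minimise sum_m a_m t_m^2 + b_m t_m over the simplex {t >= 0, sum t = 1},
# all a_m > 0. KKT: t_m = max(0, (lambda - b_m) / (2 a_m)) with lambda chosen
# so the coordinates sum to one; scan the breakpoints of the piecewise-linear
# sum in ascending order of b.
simplex_waterfill <- function(a, b) {
  m <- length(a)
  if (m == 1) return(1)
  ord <- order(b)
  a_s <- a[ord]
  b_s <- b[ord]
  inv <- 1 / (2 * a_s)
  cum_inv <- cumsum(inv)
  cum_binv <- cumsum(b_s * inv)
  t_out <- numeric(m)
  for (r in seq_len(m)) {
    lambda <- (1 + cum_binv[r]) / cum_inv[r]
    if (lambda > b_s[r] && (r == m || lambda <= b_s[r + 1])) {
      t_sorted <- pmax(0, (lambda - b_s) * inv)
      t_out[ord] <- t_sorted
      return(t_out / sum(t_sorted))
    }
  }
  # numerically flat case: fall back to uniform
  rep(1 / m, m)
}

# Block-coordinate descent for the row-simplex QP. Qs is a list of M N x N
# PSD matrices, observed an N x M logical matrix, theta0 a feasible start.
solve_row_simplex_qp <- function(Qs, observed, theta0,
                                 ridge = 1e-10, max_sweeps = 1000, tol = 1e-8) {
  n <- nrow(theta0)
  m <- length(Qs)
  theta <- theta0
  diag_q <- vapply(Qs, diag, numeric(n))        # N x M matrix of Q_m[i, i]
  grad <- vapply(seq_len(m), function(j) as.numeric(Qs[[j]] %*% theta[, j]),
                 numeric(n))                    # N x M, column j = Q_j theta_j
  converged <- FALSE
  sweeps <- 0L
  for (s in seq_len(max_sweeps)) {
    sweeps <- s
    max_delta <- 0
    for (i in seq_len(n)) {
      obs <- which(observed[i, ])
      if (length(obs) <= 1) next
      a <- diag_q[i, obs] + ridge
      b <- 2 * (grad[i, obs] - diag_q[i, obs] * theta[i, obs])
      t_new <- simplex_waterfill(a, b)
      delta <- t_new - theta[i, obs]
      if (any(delta != 0)) {
        max_delta <- max(max_delta, abs(delta))
        for (jj in seq_along(obs)) {
          j <- obs[jj]
          if (delta[jj] != 0) {
            grad[, j] <- grad[, j] + Qs[[j]][, i] * delta[jj]
          }
        }
        theta[i, obs] <- t_new
      }
    }
    if (max_delta < tol) {
      converged <- TRUE
      break
    }
  }
  objective <- sum(vapply(seq_len(m),
                          function(j) sum(theta[, j] * (Qs[[j]] %*% theta[, j])),
                          numeric(1)))
  list(theta = theta, objective = objective,
       converged = converged, sweeps = sweeps)
}
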