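# Independent oracles, deliberately implemented with different algorithms
# than the package internals they check.

# Penalized Gaussian log-likelihood the graphical lasso maximizes
# (off-diagonal penalty only).
glasso_objective <- function(Theta, S, lambda) {
  determinant(Theta, logarithm = TRUE)$modulus[1] - sum(S * Theta) -
    lambda * sum(abs(Theta[row(Theta) != col(Theta)]))
}

# Proximal-gradient solver for the graphical lasso: gradient ascent on the
# smooth part (Theta^-1 - S) with a soft-threshold proximal step on the
# off-diagonals and backtracking to stay positive definite. Slow but simple,
# and shares no code with the block-coordinate-descent implementation.
prox_grad_glasso <- function(S, lambda, step = 0.1, iters = 20000L, tol = 1e-12) {
  p <- ncol(S)
  Theta <- diag(p)
  obj <- glasso_objective(Theta, S, lambda)
  off <- row(diag(p)) != col(diag(p))
  for (i in seq_len(iters)) {
    G <- solve(Theta) - S
    t_i <- step
    repeat {
      cand <- Theta + t_i * G
      cand[off] <- sign(cand[off]) * pmax(abs(cand[off]) - t_i * lambda, 0)
      cand <- (cand + t(cand)) / 2
      ev_ok <- min(eigen(cand, symmetric = TRUE, only.values = TRUE)$values) > 1e-10
      if (ev_ok) break
      t_i <- t_i / 2
      if (t_i < 1e-12) return(list(Theta = Theta, objective = obj))
    }
    new_obj <- glasso_objective(cand, S, lambda)
    if (new_obj >= obj) {
      if (new_obj - obj < tol && i > 100) {
        Theta <- cand
        obj <- new_obj
        break
      }
      Theta <- cand
      obj <- new_obj
    } else {
      step <- step / 2
      if (step < 1e-12) break
    }
  }
  list(Theta = Theta, objective = obj)
}

# Design with columns orthonormal in the 1/n metric (X'X/n = I), mean zero:
# internal standardization leaves such a matrix unchanged, so the lasso
# solution has the soft-threshold closed form.
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * (p + 1)), n))))[, 2:(p + 1)]
  Q * sqrt(n)
}

# Closed-form p = 2 graphical lasso with off-diagonal penalty on a unit-
# diagonal S: the fitted covariance off-diagonal is s shrunk toward zero by
# lambda, and the precision off-diagonal is zero iff |s| <= lambda.
glasso_p2_closed_form <- function(s, lambda) {
  w12 <- sign(s) * max(abs(s) - lambda, 0)
  solve(matrix(c(1, w12, w12, 1), 2))
}
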