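# Penalized-regression core: coordinate-descent lasso on the Gram matrix,
# with cross-validated penalty selection. This is the shared engine behind
# the cross-lagged panel network and the graphical-lasso row subproblems.

# Coordinate descent for min_b  (1/2) b' G b - c' b + lambda * ||b||_1
# where, for a regression with standardized X, G = X'X/n and c = X'y/n.
# With p ~ 10 each update is O(p), so the solver is fast regardless of n.
lasso_gram <- function(G, c_vec, lambda, beta = NULL, tol = 1e-10,
                       max_iter = 100000L, penalty = NULL) {
  p <- length(c_vec)
  if (is.null(beta)) beta <- numeric(p)
  if (is.null(penalty)) penalty <- rep(lambda, p)
  Gb <- as.vector(G %*% beta)
  it <- 0L
  repeat {
    it <- it + 1L
    delta_max <- 0
    for (j in seq_len(p)) {
      gjj <- G[j, j]
      if (gjj <= 0) { beta[j] <- 0; next }
      r <- c_vec[j] - Gb[j] + gjj * beta[j]
      bj <- sign(r) * max(abs(r) - penalty[j], 0) / gjj
      d <- bj - beta[j]
      if (d != 0) {
        Gb <- Gb + G[, j] * d
        beta[j] <- bj
        delta_max <- max(delta_max, abs(d))
      }
    }
    if (delta_max < tol) break
    if (it >= max_iter)
      pn_convergence_error(
        "lasso coordinate descent did not converge (last max update %.3g > tol %.3g)",
        delta_max, tol)
  }
  list(beta = beta, iterations = it)
}

#' LASSO regression with unpenalized intercept
#'
#' Minimizes `(1/2n) * ||y - b0 - X beta||^2 + lambda * ||beta||_1`.
#' Predictors are standardized internally (mean 0, sd 1, population sd);
#' coefficients are returned on the original predictor scale, matching the
#' unstandardized-coefficient reporting convention of cross-lagged panel
#' networks. Coefficients shrunk to zero are exact zeros.
#'
#' @param y numeric response vector.
#' @param X numeric predictor matrix.
#' @param lambda non-negative penalty.
#' @param tol coordinate-descent convergence tolerance.
#' @return list with `beta` (original scale), `intercept`, `lambda`,
#'   `beta_std` (standardized scale), and `iterations`.
#' @export
lasso_regression <- function(y, X, lambda, tol = 1e-10) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) pn_config_error("X and y row counts differ")
  xm <- colMeans(X)
  xs <- sqrt(colMeans(sweep(X, 2, xm)^2))
  zero_sd <- xs == 0
  if (any(zero_sd)) {
    warning(sprintf("constant predictor(s) excluded: %s",
                    paste(colnames(X)[zero_sd] %||% which(zero_sd), collapse = ", ")),
            call. = FALSE)
    xs[zero_sd] <- 1
  }
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  ym <- mean(y)
  G <- crossprod(Xs) / n
  c_vec <- as.vector(crossprod(Xs, y - ym)) / n
  pen <- rep(lambda, ncol(X))
  pen[zero_sd] <- Inf   # force exact zero for excluded columns
  fit <- lasso_gram(G, c_vec, lambda, tol = tol, penalty = pen)
  beta <- fit$beta / xs
  beta[zero_sd] <- 0
  names(beta) <- colnames(X)
  list(beta = beta, intercept = ym - sum(beta * xm), lambda = lambda,
       beta_std = fit$beta, iterations = fit$iterations)
}

# lambda_max on the standardized scale: smallest penalty with all-zero fit
lasso_lambda_max <- function(y, X) {
  X <- as.matrix(X); n <- length(y)
  xm <- colMeans(X)
  xs <- sqrt(colMeans(sweep(X, 2, xm)^2))
  xs[xs == 0] <- 1
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  max(abs(crossprod(Xs, y - mean(y)))) / n
}

#' Select the LASSO penalty by k-fold cross-validation
#'
#' Minimum mean out-of-fold squared error over a log-spaced penalty grid
#' anchored at the smallest all-zero penalty. Fold assignment is a seeded
#' shuffle, so the selection is deterministic given the seed. The minimum-CV
#' rule (rather than the one-standard-error rule) is used so that small but
#' real cross-lagged paths survive selection.
#'
#' @param y response vector.
#' @param X predictor matrix.
#' @param folds number of CV folds (default 10); if `n < 2 * folds`, falls
#'   back to leave-one-out with a warning.
#' @param seed integer seed for fold assignment.
#' @param nlambda grid size.
#' @param lambda_min_ratio smallest grid value as a fraction of the maximum.
#' @return list with `lambda` (the selected value), `lambda_grid`, `cv_error`.
#' @export
cv_lambda <- function(y, X, folds = 10L, seed, nlambda = 100L,
                      lambda_min_ratio = 1e-3) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- length(y)
  if (missing(seed)) pn_config_error("cv_lambda requires a seed")
  if (n < 2L * folds) {
    warning(sprintf("n = %d too small for %d folds; using leave-one-out", n, folds),
            call. = FALSE)
    folds <- n
  }
  grid <- lambda_grid(lasso_lambda_max(y, X), nlambda, lambda_min_ratio)
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  sq_err <- matrix(NA_real_, n, length(grid))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
    # warm-started path over the descending grid
    xm <- colMeans(Xtr)
    xs <- sqrt(colMeans(sweep(Xtr, 2, xm)^2)); xs[xs == 0] <- 1
    Xs <- sweep(sweep(Xtr, 2, xm), 2, xs, "/")
    ym <- mean(ytr)
    G <- crossprod(Xs) / nrow(Xs)
    c_vec <- as.vector(crossprod(Xs, ytr - ym)) / nrow(Xs)
    beta <- numeric(ncol(X))
    for (gi in seq_along(grid)) {
      beta <- lasso_gram(G, c_vec, grid[gi], beta = beta)$beta
      b_orig <- beta / xs
      pred <- X[test, , drop = FALSE] %*% b_orig + (ym - sum(b_orig * xm))
      sq_err[test, gi] <- (y[test] - pred)^2
    }
  }
  cv_err <- colMeans(sq_err)
  best <- which.min(cv_err)  # ties resolve to the larger (sparser) penalty
  list(lambda = grid[best], lambda_grid = grid, cv_error = cv_err)
}
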