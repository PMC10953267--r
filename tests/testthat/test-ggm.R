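# Graphical lasso, EBIC selection, and the contemporaneous-network surface.

test_that("sample correlations behave like correlations", {
  set.seed(1)
  n <- 100000
  m <- matrix(rnorm(n * 3), n, 3)
  colnames(m) <- c("a", "b", "c")
  S <- sample_correlation(m)
  expect_equal(diag(S), c(a = 1, b = 1, c = 1))
  expect_lt(max(abs(S[upper.tri(S)])), 0.02)  # independent columns

  # a known population correlation is recovered
  x <- rnorm(n); y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  S2 <- sample_correlation(cbind(x = x, y = y))
  expect_equal(S2["x", "y"], 0.5, tolerance = 0.01)

  m2 <- cbind(u = rnorm(50), v = rnorm(50))
  m2 <- cbind(m2, w = m2[, "u"])
  expect_equal(sample_correlation(m2)["u", "w"], 1.0)
  expect_error(sample_correlation(cbind(a = rnorm(20), b = rep(1, 20))),
               "b", class = "panelnet_estimation_error")
})

test_that("graphical lasso handles independence and the p = 2 closed form", {
  expect_equal(graphical_lasso(diag(4), 0.1)$Theta, diag(4))

  for (s in c(0.6, -0.45, 0.2)) {
    for (lambda in c(0.1, 0.3, abs(s), abs(s) + 0.05)) {
      S <- matrix(c(1, s, s, 1), 2)
      fit <- graphical_lasso(S, lambda, tol = 1e-8)
      if (abs(s) <= lambda) {
        expect_equal(fit$Theta[1, 2], 0)
      } else {
        expect_false(fit$Theta[1, 2] == 0)
        oracle <- glasso_p2_closed_form(s, lambda)
        expect_equal(fit$Theta, oracle, tolerance = 1e-6)
        expect_equal(glasso_objective(fit$Theta, S, lambda),
                     glasso_objective(oracle, S, lambda), tolerance = 1e-8)
      }
    }
  }
})

test_that("graphical lasso matches a proximal-gradient oracle on p = 4", {
  set.seed(2)
  A <- matrix(rnorm(16), 4)
  S <- cov2cor(crossprod(A) + diag(4))
  fit <- graphical_lasso(S, 0.1, tol = 1e-8)
  oracle <- prox_grad_glasso(S, 0.1)
  expect_equal(glasso_objective(fit$Theta, S, 0.1), oracle$objective,
               tolerance = 1e-6)
})

test_that("graphical lasso solutions satisfy the KKT conditions", {
  set.seed(3)
  A <- matrix(rnorm(49), 7)
  S <- cov2cor(crossprod(A) + diag(7))
  lambda <- 0.15
  fit <- graphical_lasso(S, lambda, tol = 1e-8)
  W <- solve(fit$Theta)
  off <- upper.tri(S)
  expect_lte(max(abs(W - S)[off]), lambda + 1e-6)
  active <- fit$Theta != 0 & off
  if (any(active))
    expect_lte(max(abs(abs((W - S)[active]) - lambda)), 1e-4)
  expect_equal(diag(W), diag(S), tolerance = 1e-6)
})

test_that("the unpenalized fit reproduces textbook partial correlations", {
  set.seed(4)
  n <- 5000
  A <- matrix(rnorm(25), 5)
  X <- matrix(rnorm(n * 5), n, 5) %*% A
  S <- cor(X)
  fit <- graphical_lasso(S, 0)
  ours <- panelnet:::precision_to_partial(fit$Theta)
  Theta_ref <- solve(S)
  ref <- -Theta_ref / tcrossprod(sqrt(diag(Theta_ref)))
  diag(ref) <- 0
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("EBIC reduces to BIC at gamma zero and penalizes dense null models", {
  set.seed(5)
  S <- cor(matrix(rnorm(2000 * 6), 2000, 6))
  dense <- graphical_lasso(S, 0.001)$Theta
  sparse <- graphical_lasso(S, 0.5)$Theta   # empty on independent data
  expect_equal(sum(sparse[upper.tri(sparse)] != 0), 0)
  expect_equal(ebic_score(sparse, S, 2000, gamma = 0), -2 *
    (2000 / 2) * (determinant(sparse, TRUE)$modulus[1] - sum(S * sparse)))
  expect_lt(ebic_score(sparse, S, 2000, 0.5), ebic_score(dense, S, 2000, 0.5))
})

test_that("select_network returns an empty graph on independent data", {
  set.seed(6)
  X <- matrix(rnorm(2000 * 9), 2000, 9)
  colnames(X) <- names(study_scales())
  net <- select_network(cor(X), n = 2000)
  expect_identical(unname(net$weights), matrix(0, 9, 9))
  # edge counts along the penalty path never increase with the penalty
  path <- net$path[order(net$path$lambda), ]
  expect_true(all(diff(path$edges) <= 0))
})

test_that("select_network agrees with a brute-force EBIC search on p = 4", {
  set.seed(7)
  Theta_true <- diag(4)
  Theta_true[1, 2] <- Theta_true[2, 1] <- -0.4
  Theta_true[3, 4] <- Theta_true[4, 3] <- -0.3
  X <- matrix(rnorm(1500 * 4), 1500, 4) %*% chol(solve(Theta_true))
  S <- cor(X)
  net <- select_network(S, n = 1500, nlambda = 40)
  grid <- net$path$lambda
  brute <- vapply(grid, function(l)
    ebic_score(graphical_lasso(S, l, tol = 1e-7)$Theta, S, 1500, 0.5),
    numeric(1))
  expect_equal(net$lambda_selected, grid[which.min(brute)])
})

test_that("a chain graph is recovered with few false positives", {
  p <- 9
  Theta <- diag(p)
  for (i in seq_len(p - 1)) Theta[i, i + 1] <- Theta[i + 1, i] <- -0.4
  Sigma <- cov2cor(solve(Theta))
  truth <- abs(row(Theta) - col(Theta)) == 1
  all_true <- logical(50)
  worst_false <- numeric(50)
  for (r in seq_len(50)) {
    set.seed(100 + r)
    X <- matrix(rnorm(2000 * p), 2000, p) %*% chol(Sigma)
    net <- select_network(cor(X), n = 2000)
    found <- net$weights != 0
    all_true[r] <- all(found[truth])
    worst_false[r] <- max(abs(net$weights[!truth & upper.tri(Theta)]))
  }
  # every true edge recovered; EBIC selection along the lasso path keeps a
  # few near-zero spurious edges, an order of magnitude below the true ones
  expect_gte(mean(all_true), 0.9)
  expect_lt(max(worst_false), 0.1)
})

test_that("detected edges carry the true sign", {
  p <- 5
  Theta <- diag(p)
  Theta[1, 2] <- Theta[2, 1] <- -0.35   # positive partial correlation
  Theta[3, 4] <- Theta[4, 3] <- 0.3     # negative partial correlation
  Sigma <- cov2cor(solve(Theta))
  signs_ok <- logical(20)
  for (r in seq_len(20)) {
    set.seed(300 + r)
    X <- matrix(rnorm(5000 * p), 5000, p) %*% chol(Sigma)
    net <- select_network(cor(X), n = 5000)
    w <- net$weights
    signs_ok[r] <- (w[1, 2] == 0 || w[1, 2] > 0) && (w[3, 4] == 0 || w[3, 4] < 0)
  }
  expect_gte(mean(signs_ok), 0.95)
})

test_that("the network is invariant to rescaling input columns", {
  set.seed(8)
  X <- matrix(rnorm(800 * 4), 800, 4)
  X[, 2] <- X[, 1] * 0.5 + rnorm(800, sd = 0.8)
  net1 <- select_network(cor(X), n = 800)
  X2 <- X
  X2[, 2] <- X2[, 2] * 37
  X2[, 4] <- X2[, 4] * 0.01
  net2 <- select_network(cor(X2), n = 800)
  expect_equal(net1$weights, net2$weights)
})

test_that("edge averaging reproduces the printed reporting arithmetic", {
  w <- matrix(0, 2, 2, dimnames = list(c("anxiety", "depression"),
                                       c("anxiety", "depression")))
  w1 <- w; w1[1, 2] <- w1[2, 1] <- 0.39
  w2 <- w; w2[1, 2] <- w2[2, 1] <- 0.63
  avg <- average_edges(contemporaneous_network(w1), contemporaneous_network(w2))
  expect_equal(avg$weight_avg_rounded, 0.51)

  h <- matrix(0, 2, 2, dimnames = list(c("hostility", "harshness"),
                                       c("hostility", "harshness")))
  h1 <- h; h1[1, 2] <- h1[2, 1] <- 0.43
  h2 <- h; h2[1, 2] <- h2[2, 1] <- 0.46
  avg2 <- average_edges(contemporaneous_network(h1), contemporaneous_network(h2))
  expect_equal(avg2$weight_avg, 0.445)
  expect_equal(avg2$weight_avg_rounded, 0.45)  # ties round away from zero

  # averaging a network with itself is the identity
  avg3 <- average_edges(contemporaneous_network(h1), contemporaneous_network(h1))
  expect_equal(avg3$weight_avg, 0.43)

  rownames(h2) <- colnames(h2) <- c("a", "b")
  expect_error(average_edges(contemporaneous_network(h1),
                             contemporaneous_network(h2)),
               class = "panelnet_config_error")
})
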