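# Expected influence and temporal in-/out-prediction centralities.

mini_ggm <- function() {
  w <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  w["a", "b"] <- w["b", "a"] <- 0.5
  w["a", "c"] <- w["c", "a"] <- -0.2
  w["b", "c"] <- w["c", "b"] <- 0.1
  contemporaneous_network(w, constructs = c(a = "parenting", b = "parenting",
                                            c = "mental_health"))
}

test_that("expected influence is the signed row sum", {
  ei <- expected_influence(mini_ggm())
  expect_equal(ei$value, c(0.3, 0.6, -0.1))
  expect_equal(ei$variant, rep("none", 3))

  zero <- contemporaneous_network(matrix(0, 3, 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))))
  expect_equal(expected_influence(zero)$value, rep(0, 3))

  # independent summation oracle over a random symmetric matrix
  set.seed(1)
  w <- matrix(rnorm(36, sd = 0.2), 6, 6); w <- (w + t(w)) / 2; diag(w) <- 0
  dimnames(w) <- list(paste0("n", 1:6), paste0("n", 1:6))
  net <- contemporaneous_network(w, constructs = setNames(rep("parenting", 6),
                                                          paste0("n", 1:6)))
  oracle <- vapply(1:6, function(i) {
    s <- 0
    for (j in setdiff(1:6, i)) s <- s + w[i, j]
    s
  }, numeric(1))
  expect_equal(expected_influence(net)$value, oracle)
})

test_that("EI of a negated network is the negated EI", {
  net <- mini_ggm()
  neg <- contemporaneous_network(-net$weights, constructs = net$constructs)
  expect_equal(expected_influence(neg)$value, -expected_influence(net)$value)
})

mixed_tn <- function(d) {
  temporal_network(d, constructs = c(
    hostility = "parenting", anxiety = "mental_health",
    depression = "mental_health"))
}

test_that("in-prediction applies the exclusion rules", {
  nodes <- c("hostility", "anxiety", "depression")
  d <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  diag(d) <- 0.5
  net <- mixed_tn(d)
  expect_equal(in_prediction(net, "cross_lagged")$value, rep(0, 3))
  expect_equal(in_prediction(net, "cross_construct")$value, rep(0, 3))
  expect_equal(out_prediction(net, "cross_lagged")$value, rep(0, 3))

  d2 <- d
  d2["hostility", "depression"] <- 0.23
  d2["anxiety", "depression"] <- 0.19
  net2 <- mixed_tn(d2)
  icl <- in_prediction(net2, "cross_lagged")
  expect_equal(icl$value[icl$node == "depression"], 0.42)
  icc <- in_prediction(net2, "cross_construct")
  expect_equal(icc$value[icc$node == "depression"], 0.23)
})

test_that("out-prediction mirrors in-prediction over outgoing edges", {
  nodes <- c("hostility", "warmth", "anxiety", "depression", "aggression",
             "conduct")
  d <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  diag(d) <- 0.5
  d["hostility", "depression"] <- 0.23
  d["hostility", "aggression"] <- 0.09
  d["hostility", "anxiety"] <- 0.07
  d["hostility", "conduct"] <- 0.05
  d["hostility", "warmth"] <- -0.04   # within-construct outgoing path
  net <- temporal_network(d)
  ocl <- out_prediction(net, "cross_lagged")
  occ <- out_prediction(net, "cross_construct")
  expect_equal(ocl$value[ocl$node == "hostility"], 0.40)
  expect_equal(occ$value[occ$node == "hostility"], 0.44)

  # a single cross-construct edge contributes under both variants
  d1 <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  d1["warmth", "anxiety"] <- 0.2
  n1 <- temporal_network(d1)
  expect_equal(out_prediction(n1, "cross_lagged")$value[2], 0.2)
  expect_equal(out_prediction(n1, "cross_construct")$value[2], 0.2)
  expect_equal(in_prediction(n1, "cross_construct")$value[3], 0.2)
})

test_that("cross-construct sums are dominated when edges share a sign", {
  set.seed(2)
  nodes <- names(study_scales())
  d <- matrix(abs(rnorm(81, sd = 0.1)), 9, 9, dimnames = list(nodes, nodes))
  net <- temporal_network(d)
  for (f in list(in_prediction, out_prediction)) {
    cl <- f(net, "cross_lagged")$value
    cc <- f(net, "cross_construct")$value
    expect_true(all(abs(cc) <= abs(cl) + 1e-12))
  }
})

test_that("relabeling nodes permutes centralities consistently", {
  set.seed(3)
  nodes <- c("hostility", "warmth", "anxiety", "depression")
  d <- matrix(rnorm(16, sd = 0.1), 4, 4, dimnames = list(nodes, nodes))
  net <- temporal_network(d)
  perm <- c(3, 1, 4, 2)
  netp <- temporal_network(d[perm, perm])
  a <- out_prediction(net, "cross_construct")
  b <- out_prediction(netp, "cross_construct")
  expect_equal(b$value[match(a$node, b$node)], a$value)
})

test_that("unknown construct tags are rejected", {
  d <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  net <- temporal_network(d)  # constructs fall back to "unknown"
  expect_error(in_prediction(net, "cross_construct"),
               class = "panelnet_config_error")
})

test_that("variance-explained in-prediction matches its analytic value", {
  set.seed(4)
  n <- 20000
  nodes <- c("hostility", "depression")
  R1 <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, nodes))
  beta <- 0.4
  R2 <- cbind(rnorm(n), beta * R1[, 1] + rnorm(n, sd = 1))
  colnames(R2) <- nodes
  net <- fit_clpn(R1, R2, lambda = 0)
  ve <- variance_explained_prediction(net, R1, R2, "cross_construct")
  # single permitted predictor: R^2 ~= beta^2 var(x) / var(y)
  expect_equal(ve$value[ve$node == "depression"],
               beta^2 / (beta^2 + 1), tolerance = 0.02)
  expect_equal(ve$measure, rep("variance_explained", 2))
})

test_that("restricting predictors never increases explained variance", {
  set.seed(5)
  spec <- default_spec(n = 800, seed = 21)
  res <- simulated_residuals(spec)
  w <- panelnet:::split_waves(res)
  net <- fit_clpn(w$t1, w$t2, seed = 31)
  cl <- variance_explained_prediction(net, w$t1, w$t2, "cross_lagged")
  cc <- variance_explained_prediction(net, w$t1, w$t2, "cross_construct")
  # unrestricted R^2 (all predictors, fitted coefficients)
  full <- vapply(seq_along(net$node_labels), function(j) {
    y <- w$t2[, j]
    pred <- w$t1 %*% net$d[, j]
    1 - sum((y - mean(y) - (pred - mean(pred)))^2) / sum((y - mean(y))^2)
  }, numeric(1))
  expect_true(all(cc$value <= cl$value + 1e-10))
  expect_true(all(cl$value <= full + 1e-10))
  expect_true(all(cl$value >= -0.05 & cl$value <= 1))

  # all permitted coefficients zero gives exactly zero explained variance
  d0 <- matrix(0, 2, 2, dimnames = list(c("hostility", "depression"),
                                        c("hostility", "depression")))
  diag(d0) <- 0.5
  net0 <- temporal_network(d0)
  R <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("hostility", "depression")))
  ve0 <- variance_explained_prediction(net0, R, R, "cross_lagged")
  expect_equal(ve0$value, c(0, 0))
})
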