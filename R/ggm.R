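# Contemporaneous network estimation: correlation matrix -> graphical-lasso
# path -> EBIC selection -> partial-correlation edge weights.

new_contemporaneous_network <- function(weights, node_labels, constructs,
                                        lambda_selected, ebic_gamma, n_used,
                                        path = NULL) {
  dimnames(weights) <- list(node_labels, node_labels)
  structure(
    list(weights = weights, node_labels = node_labels, constructs = constructs,
         lambda_selected = lambda_selected, ebic_gamma = ebic_gamma,
         n_used = n_used, path = path),
    class = "contemporaneous_network"
  )
}

#' Construct a contemporaneous network from a weight matrix
#'
#' Builds the undirected partial-correlation network object directly from a
#' symmetric weight matrix — for instance a published edge table — so it can
#' be fed to [average_edges()], [expected_influence()] or the exporters
#' without re-estimation.
#'
#' @param weights symmetric numeric matrix, zero diagonal, entries in
#'   `[-1, 1]`; dimnames give the node labels.
#' @param constructs optional named construct tags (standard study nodes are
#'   recognized automatically).
#' @param n sample size behind the weights, if known.
#' @return a `contemporaneous_network`.
#' @export
contemporaneous_network <- function(weights, constructs = NULL, n = NA_integer_) {
  weights <- as.matrix(weights)
  labels <- rownames(weights) %||% paste0("V", seq_len(nrow(weights)))
  if (!isSymmetric(unname(weights), tol = 1e-10))
    pn_config_error("weights must be symmetric")
  if (any(diag(weights) != 0))
    pn_config_error("diagonal must be zero")
  if (any(abs(weights) > 1))
    pn_config_error("partial correlations must lie in [-1, 1]")
  if (is.null(constructs)) constructs <- default_constructs(labels)
  new_contemporaneous_network(weights, labels, constructs,
                              lambda_selected = NA_real_,
                              ebic_gamma = NA_real_, n_used = as.integer(n))
}

#' @export
print.contemporaneous_network <- function(x, ...) {
  E <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("Contemporaneous network (Gaussian graphical model)\n")
  cat(sprintf("  nodes: %d   edges: %d   n: %d\n",
              length(x$node_labels), E, x$n_used))
  cat(sprintf("  lambda: %.4g (EBIC gamma = %g)\n", x$lambda_selected, x$ebic_gamma))
  invisible(x)
}

#' Sample correlation matrix of residualized scores
#'
#' Pearson correlations over listwise-complete rows for one wave of a
#' residual matrix (columns suffixed `_t1`/`_t2`), or over all columns of a
#' plain matrix when `wave = NULL`.
#'
#' @param residuals residual matrix from [residualize()], or any numeric
#'   matrix.
#' @param wave `"t1"`, `"t2"`, or `NULL`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(residuals, wave = NULL) {
  m <- if (is.null(wave)) as.matrix(residuals)
       else split_waves(as.matrix(residuals))[[match.arg(wave, c("t1", "t2"))]]
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 10) pn_data_error("need >= 10 complete rows, got %d", nrow(m))
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    pn_estimation_error("zero-variance column(s): %s",
                        paste(colnames(m)[sds == 0], collapse = ", "))
  S <- stats::cor(m)
  attr(S, "n") <- nrow(m)
  S
}

#' Graphical lasso
#'
#' Estimates a sparse precision matrix by maximizing the L1-penalized
#' Gaussian log-likelihood `log det(Theta) - tr(S Theta) - lambda *
#' sum_{i != j} |Theta_ij|` (off-diagonals penalized only), using block
#' coordinate descent over rows with lasso subproblems, the standard
#' algorithm for this estimator. Entries shrunk to zero are exact zeros.
#'
#' @param S symmetric positive semi-definite correlation/covariance matrix.
#' @param lambda non-negative penalty; `lambda = 0` returns the unpenalized
#'   inverse.
#' @param tol convergence: max absolute change in the implied covariance
#'   off-diagonals below this.
#' @param max_iter outer iteration cap.
#' @param warm optional warm start (list with `W`, `Beta`) from a nearby
#'   penalty.
#' @return list with `Theta` (precision), `W` (its inverse, the fitted
#'   covariance), `iterations`, and the warm-start state.
#' @export
graphical_lasso <- function(S, lambda, tol = 1e-5, max_iter = 500L, warm = NULL) {
  S <- as.matrix(S)
  p <- ncol(S)
  if (!isSymmetric(unname(S), tol = 1e-8))
    pn_config_error("S must be symmetric")
  if (lambda < 0) pn_config_error("lambda must be non-negative")
  if (lambda == 0) {
    Theta <- solve(S)
    Theta <- (Theta + t(Theta)) / 2
    return(list(Theta = Theta, W = S, iterations = 0L,
                Beta = -sweep(Theta, 2, diag(Theta), "/") + diag(2, p)))
  }
  W <- if (!is.null(warm)) warm$W else S
  Beta <- if (!is.null(warm)) warm$Beta else matrix(0, p, p)
  diag(W) <- diag(S)  # off-diagonal-only penalty fixes the diagonal at S
  it <- 0L
  repeat {
    it <- it + 1L
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      b <- lasso_gram(W11, s12, lambda, beta = Beta[idx, j], tol = 1e-9)$beta
      Beta[idx, j] <- b
      w12 <- as.vector(W11 %*% b)
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    delta <- max(abs((W - W_old)[upper.tri(W)]))
    if (delta < tol) break
    if (it >= max_iter) {
      Theta <- glasso_theta(W, Beta, p)
      gap <- sum(diag(S %*% Theta)) - p +
        lambda * sum(abs(Theta[row(Theta) != col(Theta)]))
      pn_convergence_error(
        "graphical lasso did not converge in %d iterations (duality gap %.3g)",
        max_iter, gap)
    }
  }
  Theta <- glasso_theta(W, Beta, p)
  list(Theta = Theta, W = W, iterations = it, Beta = Beta)
}

# recover Theta from the fitted covariance W and regression coefficients;
# zeros in Beta map to exact zeros in Theta
glasso_theta <- function(W, Beta, p) {
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    b <- Beta[idx, j]
    theta_jj <- 1 / (W[j, j] - sum(W[idx, j] * b))
    Theta[j, j] <- theta_jj
    Theta[idx, j] <- ifelse(b == 0, 0, -b * theta_jj)
  }
  # symmetrize; an entry is a zero only if both column solves agree it is
  (Theta + t(Theta)) / 2 * (Theta != 0 & t(Theta) != 0 | diag(nrow(Theta)) == 1)
}

#' Extended Bayesian Information Criterion for a precision matrix
#'
#' `EBIC = -2 l + E log(n) + 4 E gamma log(p)` where
#' `l = (n/2) (log det Theta - tr(S Theta))` and `E` counts the nonzero
#' upper-triangle off-diagonal entries. `gamma = 0` reduces to the BIC.
#'
#' @param Theta precision matrix.
#' @param S the correlation matrix it was fit to.
#' @param n sample size.
#' @param gamma EBIC hyperparameter (>= 0).
#' @return the EBIC value.
#' @export
ebic_score <- function(Theta, S, n, gamma = 0.5) {
  p <- ncol(Theta)
  E <- sum(Theta[upper.tri(Theta)] != 0)
  ll <- (n / 2) * (determinant(Theta, logarithm = TRUE)$modulus[1] -
                     sum(S * Theta))
  -2 * ll + E * log(n) + 4 * E * gamma * log(p)
}

# precision matrix -> partial correlation matrix, zero diagonal
precision_to_partial <- function(Theta) {
  d <- sqrt(diag(Theta))
  P <- -Theta / tcrossprod(d)
  diag(P) <- 0
  P[Theta == 0 & row(Theta) != col(Theta)] <- 0
  P
}

#' Estimate a contemporaneous network with EBIC model selection
#'
#' Fits the graphical-lasso path over a log-spaced penalty grid (from the
#' smallest all-empty penalty down to `lambda_min_ratio` times it), scores
#' each fit by EBIC, and returns the minimizing model as partial
#' correlations `rho_ij = -Theta_ij / sqrt(Theta_ii Theta_jj)`. Ties resolve
#' toward the larger penalty (sparser network).
#'
#' @param S correlation matrix (e.g. from [sample_correlation()]).
#' @param n number of rows behind `S`.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param nlambda penalty grid size (default 100).
#' @param lambda_min_ratio grid floor as a fraction of the maximum (default
#'   0.01).
#' @param constructs named character vector of construct tags per node; the
#'   standard study scales are recognized automatically.
#' @return a `contemporaneous_network`.
#' @export
select_network <- function(S, n = attr(S, "n"), gamma = 0.5, nlambda = 100L,
                           lambda_min_ratio = 0.01, constructs = NULL) {
  S <- as.matrix(S)
  p <- ncol(S)
  labels <- colnames(S) %||% paste0("V", seq_len(p))
  if (is.null(constructs)) constructs <- default_constructs(labels)
  if (is.null(n)) pn_config_error("sample size n is required")
  off <- abs(S[upper.tri(S)])
  grid <- lambda_grid(max(off), nlambda, lambda_min_ratio)
  ebic <- numeric(length(grid))
  fits <- vector("list", length(grid))
  warm <- NULL
  for (i in seq_along(grid)) {
    fit <- graphical_lasso(S, grid[i], warm = warm)
    warm <- fit
    fits[[i]] <- fit
    ebic[i] <- ebic_score(fit$Theta, S, n, gamma)
  }
  best <- which.min(ebic)  # descending grid: first minimum = largest lambda
  weights <- precision_to_partial(fits[[best]]$Theta)
  new_contemporaneous_network(
    weights, labels, constructs, lambda_selected = grid[best],
    ebic_gamma = gamma, n_used = n,
    path = data.frame(lambda = grid, ebic = ebic,
                      edges = vapply(fits, function(f)
                        sum(f$Theta[upper.tri(f$Theta)] != 0), numeric(1)))
  )
}

# construct tags for the standard study node set; anything else must be
# supplied explicitly where constructs matter
default_constructs <- function(labels) {
  std <- constructs_of(study_scales(include_discipline = TRUE))
  out <- std[labels]
  names(out) <- labels
  out[is.na(out)] <- "unknown"
  out
}

#' Average edge weights across the two contemporaneous networks
#'
#' The per-pair mean of the T1 and T2 partial correlations, rounded
#' half-away-from-zero to two decimals for reporting. The displayed table
#' keeps pairs whose weight exceeds `threshold` in absolute value at either
#' wave; the full unrounded table is retained in attribute `"all_pairs"`.
#'
#' @param net_t1,net_t2 `contemporaneous_network` objects with identical
#'   node labels.
#' @param threshold display cutoff (default 0.01).
#' @return data frame with columns node_a, node_b, weight_t1, weight_t2,
#'   weight_avg, weight_avg_rounded, sorted by descending average.
#' @export
average_edges <- function(net_t1, net_t2, threshold = 0.01) {
  if (!identical(net_t1$node_labels, net_t2$node_labels))
    pn_config_error("node labels differ between the two networks")
  w1 <- net_t1$weights; w2 <- net_t2$weights
  ut <- which(upper.tri(w1), arr.ind = TRUE)
  tab <- data.frame(
    node_a = net_t1$node_labels[ut[, 1]],
    node_b = net_t1$node_labels[ut[, 2]],
    weight_t1 = w1[ut], weight_t2 = w2[ut],
    weight_avg = (w1[ut] + w2[ut]) / 2
  )
  tab$weight_avg_rounded <- round_half_out(tab$weight_avg, 2)
  tab <- tab[order(-tab$weight_avg), ]
  rownames(tab) <- NULL
  shown <- tab[abs(tab$weight_t1) > threshold | abs(tab$weight_t2) > threshold, ]
  rownames(shown) <- NULL
  attr(shown, "all_pairs") <- tab
  shown
}
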