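# Temporal network estimation: cross-lagged panel network via node-wise
# cross-validated LASSO regression of each T2 score on all T1 scores.

new_temporal_network <- function(d, node_labels, constructs, lambda_per_node,
                                 cv_seed, intercepts = NULL) {
  dimnames(d) <- list(node_labels, node_labels)
  structure(
    list(d = d, node_labels = node_labels, constructs = constructs,
         lambda_per_node = lambda_per_node, cv_seed = cv_seed,
         intercepts = intercepts),
    class = "temporal_network"
  )
}

#' Construct a temporal network from a coefficient matrix
#'
#' Builds the directed cross-lagged network object from a coefficient matrix
#' (`d[i, j]` = T1 node i predicting T2 node j, autoregressive diagonal),
#' e.g. a published edge table or a simulation's true transition matrix.
#'
#' @param d numeric p x p matrix with dimnames giving the node labels.
#' @param constructs optional named construct tags (standard study nodes are
#'   recognized automatically).
#' @return a `temporal_network`.
#' @export
temporal_network <- function(d, constructs = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) pn_config_error("d must be square")
  labels <- rownames(d) %||% paste0("V", seq_len(nrow(d)))
  if (is.null(constructs)) constructs <- default_constructs(labels)
  new_temporal_network(d, labels, constructs,
                       lambda_per_node = rep(NA_real_, nrow(d)),
                       cv_seed = NA_integer_)
}

#' @export
print.temporal_network <- function(x, ...) {
  off <- x$d; diag(off) <- 0
  cat("Temporal network (cross-lagged panel network, T1 -> T2)\n")
  cat(sprintf("  nodes: %d   cross-lagged edges: %d   cv seed: %s\n",
              length(x$node_labels), sum(off != 0),
              format(x$cv_seed)))
  cat(sprintf("  autoregressive paths: %s\n",
              paste(sprintf("%.2f", diag(x$d)), collapse = " ")))
  invisible(x)
}

#' Fit a cross-lagged panel network
#'
#' Each T2 node is regressed on all nine T1 nodes with a LASSO penalty tuned
#' per node by seeded k-fold cross-validation; `d[i, j]` is the
#' (unstandardized) coefficient of T1 node `i` predicting T2 node `j`, with
#' the autoregressive paths on the diagonal. Columns are fit independently.
#'
#' @param residuals_t1,residuals_t2 row-aligned n x p matrices of
#'   covariate-residualized scores (same participants in both).
#' @param seed master seed; per-node CV seeds are derived from it.
#' @param folds CV folds per node (default 10).
#' @param nlambda penalty grid size.
#' @param lambda optional fixed penalty (scalar or per-node vector)
#'   bypassing cross-validation, e.g. `lambda = 0` for node-wise OLS.
#' @param constructs construct tags per node (standard study nodes are
#'   recognized automatically).
#' @return a `temporal_network`.
#' @export
fit_clpn <- function(residuals_t1, residuals_t2, seed, folds = 10L,
                     nlambda = 100L, lambda = NULL, constructs = NULL) {
  X <- as.matrix(residuals_t1); Y <- as.matrix(residuals_t2)
  if (nrow(X) != nrow(Y) || ncol(X) != ncol(Y))
    pn_config_error("residual matrices must be row- and column-aligned")
  labels <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  # T2 columns may arrive in any order; align them to the T1 labels so the
  # fitted network is invariant to column permutations of either wave
  if (!is.null(colnames(Y))) {
    if (!setequal(colnames(Y), labels))
      pn_config_error("T1 and T2 column names do not match")
    Y <- Y[, labels, drop = FALSE]
  }
  if (is.null(constructs)) constructs <- default_constructs(labels)
  if (missing(seed) && is.null(lambda))
    pn_config_error("fit_clpn requires a master seed for cross-validation")
  if (missing(seed)) seed <- 0L
  p <- ncol(X)
  d <- matrix(0, p, p)
  lams <- numeric(p)
  intercepts <- numeric(p)
  for (j in seq_len(p)) {
    res <- tryCatch({
      # seed stream keyed to the node label, so reordering columns cannot
      # change any node's selection
      lam_j <- if (!is.null(lambda)) rep_len(lambda, p)[j]
               else cv_lambda(Y[, j], X, folds = folds,
                              seed = derive_seed(seed, label_seed_index(labels[j])),
                              nlambda = nlambda)$lambda
      fit <- lasso_regression(Y[, j], X, lam_j)
      list(lambda = lam_j, fit = fit)
    }, panelnet_error = function(e)
      pn_convergence_error("node '%s': %s", labels[j], conditionMessage(e)))
    d[, j] <- res$fit$beta
    lams[j] <- res$lambda
    intercepts[j] <- res$fit$intercept
  }
  names(lams) <- labels
  new_temporal_network(d, labels, constructs, lams, seed, intercepts)
}

#' Filter and sort directed edges for reporting
#'
#' Off-diagonal (cross-lagged) entries whose absolute weight exceeds the
#' threshold, sorted by descending coefficient and rounded
#' half-away-from-zero to two decimals; autoregressive paths are excluded
#' from the table (they are flagged, not displayed, by convention).
#'
#' @param net a `temporal_network`.
#' @param threshold absolute-weight display cutoff (default 0.01).
#' @return data frame with columns from_node, to_node, d, d_rounded.
#' @export
filter_edges <- function(net, threshold = 0.01) {
  d <- net$d
  idx <- which(row(d) != col(d) & abs(d) > threshold, arr.ind = TRUE)
  tab <- data.frame(
    from_node = net$node_labels[idx[, 1]],
    to_node = net$node_labels[idx[, 2]],
    d = d[idx]
  )
  tab <- tab[order(-tab$d), ]
  tab$d_rounded <- round_half_out(tab$d, 2)
  rownames(tab) <- NULL
  tab
}

#' Full directed edge table including autoregressive paths
#'
#' @param net a `temporal_network`.
#' @return data frame with columns from_node, to_node, d, is_autoregressive.
#' @export
temporal_edge_table <- function(net) {
  d <- net$d
  idx <- which(d != 0, arr.ind = TRUE)
  tab <- data.frame(
    from_node = net$node_labels[idx[, 1]],
    to_node = net$node_labels[idx[, 2]],
    d = d[idx],
    is_autoregressive = idx[, 1] == idx[, 2]
  )
  tab <- tab[order(tab$is_autoregressive, -tab$d), ]
  rownames(tab) <- NULL
  tab
}
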