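# Centrality indices: expected influence for contemporaneous networks,
# in-/out-prediction (cross-lagged and cross-construct) for the temporal
# network, plus the variance-explained reading of in-prediction.

centrality_table <- function(node, index_type, variant, value,
                             measure = "edge_sum") {
  data.frame(node = node, index_type = index_type, variant = variant,
             value = as.numeric(value), measure = measure)
}

#' Expected influence
#'
#' The signed sum of a node's edge weights to all other nodes (one-step
#' expected influence). Unlike strength centrality, negative edges count
#' negatively.
#'
#' @param net a `contemporaneous_network`.
#' @return centrality table with one EI row per node.
#' @export
expected_influence <- function(net) {
  ei <- rowSums(net$weights)  # diagonal is zero by construction
  centrality_table(net$node_labels, "EI", "none", ei)
}

# permitted-predictor mask for node j under a variant
permitted_in <- function(net, j, variant) {
  p <- length(net$node_labels)
  keep <- seq_len(p) != j
  if (variant == "cross_construct")
    keep <- keep & net$constructs != net$constructs[j]
  keep
}

#' In-prediction centrality
#'
#' How much a T2 node is predicted by the T1 nodes: the signed sum of its
#' incoming cross-lagged edge weights. The `cross_lagged` variant excludes
#' only the node's own autoregressive path; `cross_construct` additionally
#' excludes paths from nodes of the same construct, isolating the influence
#' of the other construct (parenting on mental health or vice versa).
#'
#' @param net a `temporal_network` with construct tags.
#' @param variant `"cross_lagged"` or `"cross_construct"`.
#' @return centrality table with one row per node.
#' @export
in_prediction <- function(net, variant = c("cross_lagged", "cross_construct")) {
  variant <- match.arg(variant)
  check_constructs(net)
  vals <- vapply(seq_along(net$node_labels), function(j)
    sum(net$d[permitted_in(net, j, variant), j]), numeric(1))
  centrality_table(net$node_labels, "in_prediction", variant, vals)
}

#' Out-prediction centrality
#'
#' How much a T1 node predicts the T2 nodes: the signed sum of its outgoing
#' cross-lagged edge weights, under the same exclusion rules as
#' [in_prediction()].
#'
#' @inheritParams in_prediction
#' @return centrality table with one row per node.
#' @export
out_prediction <- function(net, variant = c("cross_lagged", "cross_construct")) {
  variant <- match.arg(variant)
  check_constructs(net)
  vals <- vapply(seq_along(net$node_labels), function(i)
    sum(net$d[i, permitted_in(net, i, variant)]), numeric(1))
  centrality_table(net$node_labels, "out_prediction", variant, vals)
}

check_constructs <- function(net) {
  if (any(!net$constructs %in% c("parenting", "mental_health")))
    pn_config_error("unknown construct tag(s): %s",
                    paste(unique(net$constructs[
                      !net$constructs %in% c("parenting", "mental_health")]),
                      collapse = ", "))
}

#' Variance-explained in-prediction
#'
#' The proportion of a T2 node's variance accounted for by the permitted T1
#' predictors: R-squared of the fitted linear predictor with coefficients
#' taken from the cross-lagged panel network fit and non-permitted
#' coefficients zeroed. This is the variance-based reading of
#' in-prediction; the edge-sum reading is [in_prediction()].
#'
#' @param net a fitted `temporal_network`.
#' @param residuals_t1,residuals_t2 the data the network was fit on.
#' @param variant `"cross_lagged"` or `"cross_construct"`.
#' @return centrality table with one row per node
#'   (`measure = "variance_explained"`).
#' @export
variance_explained_prediction <- function(net, residuals_t1, residuals_t2,
                                          variant = c("cross_lagged",
                                                      "cross_construct")) {
  variant <- match.arg(variant)
  check_constructs(net)
  X <- as.matrix(residuals_t1); Y <- as.matrix(residuals_t2)
  if (nrow(X) != nrow(Y) || ncol(X) != length(net$node_labels))
    pn_config_error("data dimensions do not match the network")
  vals <- vapply(seq_along(net$node_labels), function(j) {
    keep <- permitted_in(net, j, variant)
    b <- net$d[, j] * keep
    pred <- X %*% b
    y <- Y[, j]
    1 - sum((y - mean(y) - (pred - mean(pred)))^2) / sum((y - mean(y))^2)
  }, numeric(1))
  centrality_table(net$node_labels, "in_prediction", variant, vals,
                   measure = "variance_explained")
}
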