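# Network exports (GraphML, JSON adjacency) and the shared force-directed
# layout used to draw both contemporaneous networks with identical node
# positions.

network_to_igraph <- function(net) {
  if (inherits(net, "contemporaneous_network")) {
    g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
  } else if (inherits(net, "temporal_network")) {
    g <- igraph::graph_from_adjacency_matrix(net$d, mode = "directed",
                                             weighted = TRUE, diag = TRUE)
    el <- igraph::as_edgelist(g)
    igraph::E(g)$is_autoregressive <- el[, 1] == el[, 2]
  } else {
    pn_config_error("not a network object")
  }
  igraph::V(g)$construct <- unname(net$constructs[igraph::V(g)$name])
  g
}

#' Export a network to GraphML
#'
#' Nodes carry a `construct` attribute, edges a `weight` attribute;
#' temporal-network autoregressive edges are flagged with
#' `is_autoregressive` so renderers can hide them.
#'
#' @param net a `contemporaneous_network` or `temporal_network`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_graphml <- function(net, path) {
  igraph::write_graph(network_to_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Export a network as a JSON adjacency object
#'
#' @param net a `contemporaneous_network` or `temporal_network`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_json <- function(net, path) {
  W <- if (inherits(net, "contemporaneous_network")) net$weights else net$d
  jsonlite::write_json(
    list(nodes = net$node_labels,
         constructs = unname(net$constructs[net$node_labels]),
         directed = inherits(net, "temporal_network"),
         weights = unname(apply(W, 1, as.numeric, simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Shared force-directed layout for two networks
#'
#' Computes a Fruchterman-Reingold layout on the element-wise mean of the
#' two absolute weight matrices, so the same node occupies the same position
#' in both network drawings. Coordinates are normalized to the unit square.
#' Deterministic given the seed (including for an empty averaged network,
#' which gets a seeded random placement).
#'
#' @param net_t1,net_t2 networks over the same node set.
#' @param seed integer seed.
#' @return data frame with columns node, x, y.
#' @export
average_layout <- function(net_t1, net_t2, seed = 1L) {
  if (!identical(net_t1$node_labels, net_t2$node_labels))
    pn_config_error("node labels differ between the two networks")
  W1 <- if (inherits(net_t1, "temporal_network")) net_t1$d else net_t1$weights
  W2 <- if (inherits(net_t2, "temporal_network")) net_t2$d else net_t2$weights
  A <- (abs(W1) + abs(W2)) / 2
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  xy <- if (igraph::ecount(g) > 0)
    igraph::layout_with_fr(g, weights = igraph::E(g)$weight, niter = 500)
  else igraph::layout_randomly(g)
  norm01 <- function(v) if (diff(range(v)) < 1e-12) rep(0.5, length(v))
                        else (v - min(v)) / diff(range(v))
  data.frame(node = net_t1$node_labels, x = norm01(xy[, 1]), y = norm01(xy[, 2]))
}
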