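#' Node centrality indices on a weighted network
#'
#' Strength is the sum of absolute incident edge weights. Closeness
#' and Betweenness are shortest-path indices where an edge of weight
#' `w` has length `1 / |w|` (stronger association = shorter distance):
#' Closeness is the inverse of the total distance from the node to all
#' others (0 for a node disconnected from any other), Betweenness the
#' Brandes count of geodesics passing through the node, with tied
#' geodesics splitting credit equally.
#'
#' @name centrality
#' @param W Symmetric edge-weight matrix with zero diagonal, or an
#'   `rsi_network`.
#' @return Numeric vector, one value per node.
NULL

centrality_weights <- function(W) {
  if (inherits(W, "rsi_network")) W <- W$W
  W <- as.matrix(W)
  if (max(abs(W - t(W))) > 1e-8 || any(diag(W) != 0)) {
    abort("W must be symmetric with a zero diagonal")
  }
  W
}

as_length_graph <- function(W) {
  A <- abs(W)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$length <- 1 / igraph::E(g)$weight
  g
}

#' @rdname centrality
#' @export
node_strength <- function(W) {
  W <- centrality_weights(W)
  colSums(abs(W))
}

#' @rdname centrality
#' @export
node_closeness <- function(W) {
  W <- centrality_weights(W)
  g <- as_length_graph(W)
  d <- igraph::distances(g, weights = igraph::E(g)$length)
  tot <- rowSums(d)
  out <- ifelse(is.finite(tot) & tot > 0, 1 / tot, 0)
  setNames(as.numeric(out), colnames(W))
}

#' @rdname centrality
#' @export
node_betweenness <- function(W) {
  W <- centrality_weights(W)
  g <- as_length_graph(W)
  b <- igraph::betweenness(g, weights = igraph::E(g)$length,
                           directed = FALSE)
  setNames(as.numeric(b), colnames(W))
}

rescale01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Centrality table for a network
#'
#' All three indices per node, raw and min-max rescaled to \[0, 1\]
#' (1 = most important node, 0 = least). Comparisons between groups
#' operate on the raw values; the rescaled columns are the
#' presentation scale.
#'
#' @param network An `rsi_network` or a symmetric edge-weight matrix.
#' @param network_id Label recorded in the output (e.g. `"whole"`).
#' @return Tibble with columns `network_id`, `node`, `strength`,
#'   `closeness`, `betweenness` and their `_scaled` versions.
#' @export
centrality_table <- function(network, network_id = "network") {
  W <- centrality_weights(network)
  nodes <- colnames(W) %||% rsi_items(ncol(W))
  tibble::tibble(
    network_id = network_id,
    node = nodes,
    strength = unname(node_strength(W)),
    closeness = unname(node_closeness(W)),
    betweenness = unname(node_betweenness(W))
  ) |>
    dplyr::mutate(
      strength_scaled = rescale01(.data$strength),
      closeness_scaled = rescale01(.data$closeness),
      betweenness_scaled = rescale01(.data$betweenness)
    )
}
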