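#' Binarize a thresholded connectivity matrix into a brain graph
#'
#' An edge exists wherever a retained (nonzero) weight survives thresholding.
#' Binarization is idempotent: applying it to an adjacency matrix returns the
#' same graph.
#'
#' @param C A thresholded `connectivity_matrix`, or a symmetric numeric
#'   matrix.
#' @return A `brain_graph`: list with binary `adjacency` (zero diagonal) and
#'   `node_names`.
#' @export
brain_graph <- function(C) {
  vals <- if (inherits(C, "connectivity_matrix")) C$values else C
  abort_if(!isTRUE(all.equal(vals, t(vals), tolerance = 1e-8)),
           "adjacency must be symmetric")
  adj <- (vals != 0) * 1
  diag(adj) <- 0
  nm <- rownames(vals) %||%
    (if (inherits(C, "connectivity_matrix")) C$channel_names else NULL) %||%
    paste0("n", seq_len(nrow(adj)))
  dimnames(adj) <- list(nm, nm)
  structure(list(adjacency = adj, node_names = nm), class = "brain_graph")
}

#' @export
print.brain_graph <- function(x, ...) {
  cat(sprintf("brain_graph: %d nodes, %d edges\n", nrow(x$adjacency),
              sum(x$adjacency[upper.tri(x$adjacency)])))
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
}

#' Node degree centrality
#'
#' `k_i / (N - 1)`: the fraction of possible neighbours each node connects to.
#'
#' @param g A `brain_graph` with at least 2 nodes.
#' @return Named numeric vector in [0, 1].
#' @export
degree_centrality <- function(g) {
  n <- nrow(g$adjacency)
  abort_if(n < 2, "degree centrality needs at least 2 nodes")
  stats::setNames(rowSums(g$adjacency) / (n - 1), g$node_names)
}

#' Node betweenness centrality
#'
#' Pair-dependency sum normalized by `(N-1)(N-2)/2`: for each unordered pair
#' (h, j), the fraction of shortest h-j paths passing through the node.
#' Unreachable pairs contribute zero. Shortest paths are unweighted hop
#' counts.
#'
#' @param g A `brain_graph` with at least 3 nodes.
#' @return Named numeric vector in [0, 1].
#' @export
betweenness_centrality <- function(g) {
  n <- nrow(g$adjacency)
  abort_if(n < 3, "betweenness centrality needs at least 3 nodes")
  b <- igraph::betweenness(as_igraph(g), directed = FALSE, normalized = TRUE)
  stats::setNames(as.numeric(b), g$node_names)
}

#' Node clustering coefficient
#'
#' `2 t_i / (k_i (k_i - 1))`: the fraction of realized links among each node's
#' neighbours. Nodes of degree < 2 are assigned 0.
#'
#' @param g A `brain_graph`.
#' @return Named numeric vector in [0, 1].
#' @export
clustering_coefficient <- function(g) {
  cc <- igraph::transitivity(as_igraph(g), type = "local", isolates = "zero")
  stats::setNames(as.numeric(cc), g$node_names)
}

# Inverse-shortest-path efficiency of an adjacency matrix (mean over ordered
# node pairs of 1/d, 1/Inf = 0); the Latora-Marchiori efficiency.
adjacency_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- igraph::distances(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Node local efficiency
#'
#' Efficiency of the subgraph induced by each node's neighbours: how well
#' information spreads around a node when it is removed. Nodes with fewer
#' than 2 neighbours are assigned 0.
#'
#' @param g A `brain_graph`.
#' @return Named numeric vector in [0, 1].
#' @export
local_efficiency <- function(g) {
  adj <- g$adjacency
  out <- numeric(nrow(adj))
  for (i in seq_len(nrow(adj))) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) < 2) next
    out[i] <- adjacency_efficiency(adj[nb, nb, drop = FALSE])
  }
  stats::setNames(out, g$node_names)
}

#' Graph global efficiency
#'
#' Mean over nodes of the mean inverse shortest-path length to every other
#' node (1/Inf = 0 for unreachable pairs): the network's overall capacity for
#' parallel information transfer.
#'
#' @param g A `brain_graph` with at least 2 nodes.
#' @return A single value in [0, 1].
#' @export
global_efficiency <- function(g) {
  abort_if(nrow(g$adjacency) < 2, "global efficiency needs at least 2 nodes")
  adjacency_efficiency(g$adjacency)
}

#' All node metrics of a brain graph as a table
#'
#' @param g A `brain_graph`.
#' @param band,group Optional annotation columns.
#' @return A data.frame with one row per node (degree, betweenness,
#'   clustering, local efficiency) and the graph's global efficiency in
#'   `attr(, "global_efficiency")`.
#' @export
node_metric_table <- function(g, band = NA_character_, group = NA_character_) {
  tbl <- data.frame(node = g$node_names,
                    degree_centrality = as.numeric(degree_centrality(g)),
                    betweenness_centrality = as.numeric(betweenness_centrality(g)),
                    clustering_coefficient = as.numeric(clustering_coefficient(g)),
                    local_efficiency = as.numeric(local_efficiency(g)),
                    band = band, group = group,
                    stringsAsFactors = FALSE)
  attr(tbl, "global_efficiency") <- global_efficiency(g)
  tbl
}
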