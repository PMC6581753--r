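#' @title Local graph metrics for brain networks
#' @description
#' Binary and weighted variants of the four local metrics standard in
#' connectomics (degree/strength, clustering coefficient, local efficiency,
#' betweenness centrality), following the Rubinov-Sporns conventions.
#' Weighted variants first rescale weights by the largest weight in the
#' (thresholded) graph, and weighted shortest paths use edge length `1/w`
#' because fiber counts are affinities; with all-equal weights every weighted
#' metric reduces exactly to its binary counterpart on the same support.
#' @name local_metrics
NULL

metric_vector <- function(values, metric, weighted, labels) {
  names(values) <- labels
  structure(values, metric = metric, weighted = weighted,
            class = c("node_metric_vector", "numeric"))
}

# weights rescaled by the network maximum; binary support matrix alongside
graph_matrices <- function(G, weighted) {
  stopifnot(inherits(G, "brain_graph"))
  a <- (G$adjacency > 0) * 1
  if (weighted) {
    mx <- max(G$adjacency)
    w <- if (mx > 0) G$adjacency / mx else G$adjacency
  } else {
    w <- a
  }
  list(a = a, w = w)
}

# igraph with distances measured as 1/w (affinity -> length)
length_graph <- function(w_adj) {
  len <- w_adj
  len[len > 0] <- 1 / len[len > 0]
  igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Node degree / strength
#'
#' Binary: number of connections of each node. Weighted (strength): sum of
#' the node's raw edge weights (no rescaling — strength keeps fiber-count
#' units).
#'
#' @param G A `brain_graph`.
#' @param weighted Use edge weights.
#' @return A `node_metric_vector` of length q.
#' @export
node_degree <- function(G, weighted = FALSE) {
  stopifnot(inherits(G, "brain_graph"))
  vals <- if (weighted) rowSums(G$adjacency) else rowSums(G$adjacency > 0)
  metric_vector(vals, "degree", weighted, G$node_labels)
}

#' Clustering coefficient
#'
#' Binary: fraction of realized triangles around each node,
#' `CC_i = 2 t_i / (k_i (k_i - 1))`. Weighted: triangles are replaced by
#' triangle intensities `(w~_ij w~_jh w~_hi)^(1/3)` with weights rescaled by
#' the network maximum. Nodes with fewer than two neighbors get 0.
#'
#' @inheritParams node_degree
#' @return A `node_metric_vector` of length q.
#' @export
clustering_coefficient <- function(G, weighted = FALSE) {
  gm <- graph_matrices(G, weighted)
  k <- rowSums(gm$a)
  w3 <- gm$w^(1 / 3)
  t_i <- diag(w3 %*% w3 %*% w3) / 2
  denom <- k * (k - 1)
  vals <- ifelse(denom > 0, 2 * t_i / denom, 0)
  metric_vector(vals, "clustering", weighted, G$node_labels)
}

#' Local efficiency
#'
#' Global efficiency of each node's neighborhood: for node i with neighbors
#' `N_i`, average inverse shortest-path length between pairs of neighbors,
#' with paths restricted to run inside `N_i`. Binary:
#' `E_i = sum_{j != h in N_i} [d_jh(N_i)]^-1 / (k_i (k_i - 1))`; unreachable
#' pairs contribute 0. The weighted variant multiplies each term by the
#' cube-rooted product of the rescaled incident weights,
#' `(w~_ij w~_ih)^(1/3)`, and measures restricted shortest paths on edge
#' lengths `1/w~`; with all-equal weights it reduces to the binary form.
#' Nodes with fewer than two neighbors get 0.
#'
#' @inheritParams node_degree
#' @return A `node_metric_vector` of length q.
#' @export
local_efficiency <- function(G, weighted = FALSE) {
  gm <- graph_matrices(G, weighted)
  q <- nrow(gm$a)
  vals <- numeric(q)
  for (i in seq_len(q)) {
    nb <- which(gm$a[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub_w <- gm$w[nb, nb, drop = FALSE]
    g_sub <- length_graph(sub_w)
    d <- igraph::distances(g_sub)
    inv_d <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
    inc <- gm$w[i, nb]^(1 / 3)
    num <- outer(inc, inc) * inv_d
    diag(num) <- 0
    vals[i] <- sum(num) / (k * (k - 1))
  }
  metric_vector(vals, "efficiency", weighted, G$node_labels)
}

#' Betweenness centrality
#'
#' Fraction of all shortest paths that pass through each node:
#' `BC_i = 1/((n-1)(n-2)) * sum_{h != j, both != i} rho_hj(i) / rho_hj` over
#' ordered pairs, where `rho_hj` counts shortest paths between h and j and
#' pairs with no path contribute 0. The weighted variant measures path
#' length on `1/w`; path counts and pass-through counts are otherwise
#' identical in definition.
#'
#' @inheritParams node_degree
#' @return A `node_metric_vector` of length q.
#' @export
betweenness_centrality <- function(G, weighted = FALSE) {
  gm <- graph_matrices(G, weighted)
  q <- nrow(gm$a)
  if (q < 3) {
    return(metric_vector(numeric(q), "betweenness", weighted, G$node_labels))
  }
  g <- length_graph(gm$w)
  bc_pairs <- igraph::betweenness(g, directed = FALSE,
                                  weights = igraph::E(g)$weight)
  vals <- 2 * bc_pairs / ((q - 1) * (q - 2))
  metric_vector(unname(vals), "betweenness", weighted, G$node_labels)
}

#' All four local metrics together
#'
#' Computes degree, betweenness centrality, clustering coefficient and local
#' efficiency on the same graph; the output order `[D, BC, CC, E]` is fixed
#' and is the column order used by the all-graphs feature condition.
#'
#' @inheritParams node_degree
#' @return Named list of `node_metric_vector`s: `D`, `BC`, `CC`, `E`.
#' @export
all_local_metrics <- function(G, weighted = FALSE) {
  list(D = node_degree(G, weighted),
       BC = betweenness_centrality(G, weighted),
       CC = clustering_coefficient(G, weighted),
       E = local_efficiency(G, weighted))
}
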