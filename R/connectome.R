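#' Construct a connectivity matrix
#'
#' A connectivity matrix holds the raw structural connectome: a square,
#' symmetric, non-negative matrix of fiber counts between parcellated brain
#' regions, with a zero diagonal.
#'
#' @param values Square numeric matrix of non-negative connection weights.
#' @param node_labels Optional character vector of region names (defaults to
#'   existing dimnames or `"node_1"` style labels).
#' @return An object of class `connectivity_matrix` with fields `values`,
#'   `node_labels` and `q` (node count).
#' @export
connectivity_matrix <- function(values, node_labels = NULL) {
  values <- as.matrix(values)
  q <- nrow(values)
  if (q < 2L || ncol(values) != q)
    stop("connectivity matrix must be square with at least 2 nodes")
  if (anyNA(values) || any(!is.finite(values)))
    stop("connectivity matrix contains missing or non-finite entries")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative entry at (%d, %d)", bad[1L], bad[2L]))
  }
  asym <- abs(values - t(values))
  if (any(asym > 1e-9)) {
    bad <- which(asym > 1e-9, arr.ind = TRUE)[1L, ]
    stop(sprintf("matrix is not symmetric: entries (%d, %d) and (%d, %d) differ",
                 bad[1L], bad[2L], bad[2L], bad[1L]))
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (is.null(node_labels)) {
    node_labels <- rownames(values)
    if (is.null(node_labels)) node_labels <- paste0("node_", seq_len(q))
  }
  if (length(node_labels) != q)
    stop("node_labels length does not match matrix dimension")
  dimnames(values) <- list(node_labels, node_labels)
  structure(list(values = values, node_labels = node_labels, q = q),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix: %d nodes, %d positive edges, total fiber count %s>\n",
              x$q, sum(x$values[upper.tri(x$values)] > 0),
              format(sum(x$values) / 2)))
  invisible(x)
}

#' Read a connectivity matrix from a delimited text file
#'
#' Reads a whitespace- or comma-delimited square numeric matrix. Asymmetry
#' within a 1e-9 tolerance is symmetrized by averaging; larger asymmetry and
#' any negative or missing cell is an error naming the offending entry.
#'
#' @param path Path to the matrix file.
#' @param node_labels Optional region names.
#' @return A [connectivity_matrix()].
#' @export
load_connectivity <- function(path, node_labels = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    l <- gsub(",", " ", l, fixed = TRUE)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L || ncols[1L] != length(rows))
    stop(sprintf("'%s' does not parse as a square matrix (%d rows, %s columns)",
                 path, length(rows), paste(unique(ncols), collapse = "/")))
  values <- do.call(rbind, rows)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row %d, column %d of '%s'",
                 bad[1L], bad[2L], path))
  }
  connectivity_matrix(values, node_labels = node_labels)
}

#' Write a connectivity matrix as whitespace-delimited text
#'
#' @param A A [connectivity_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(A, path) {
  stopifnot(inherits(A, "connectivity_matrix"))
  utils::write.table(A$values, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Proportional edge thresholding
#'
#' Sparsifies a connectome to the fraction `tau` of strongest possible edges:
#' with q nodes there are (q^2 - q)/2 node pairs, and the operator retains
#' exactly `T = floor((q^2 - q) * tau / 2)` edges of largest weight, zeroing
#' everything else. Only pairs with positive fiber count are eligible, so
#' fewer than `T` edges are kept when the raw graph is sparser than `tau`.
#' Ties at the cutoff weight are broken by lexicographic node-pair order so
#' that the result is deterministic and the kept edge set is monotone in
#' `tau`.
#'
#' @param A A [connectivity_matrix()].
#' @param tau Fraction of possible edges to keep, in `[0, 1]`.
#' @return A `brain_graph`: list with `adjacency` (kept weights), `weighted`
#'   flag, `tau`, `n_edges_kept` and `node_labels`.
#' @export
threshold_graph <- function(A, tau) {
  stopifnot(inherits(A, "connectivity_matrix"))
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0 || tau > 1)
    stop("tau must be a single number in [0, 1]")
  q <- A$q
  T_keep <- floor((q^2 - q) * tau / 2)
  ut <- which(upper.tri(A$values), arr.ind = TRUE)
  w <- A$values[ut]
  eligible <- which(w > 0)
  # descending weight, ties by (row, col) lexicographic order
  ord <- eligible[order(-w[eligible], ut[eligible, 1L], ut[eligible, 2L])]
  kept <- ord[seq_len(min(T_keep, length(ord)))]
  adj <- matrix(0, q, q, dimnames = dimnames(A$values))
  adj[ut[kept, , drop = FALSE]] <- w[kept]
  adj <- adj + t(adj)
  structure(list(adjacency = adj, weighted = TRUE, tau = tau,
                 n_edges_kept = length(kept), node_labels = A$node_labels),
            class = "brain_graph")
}

#' @export
print.brain_graph <- function(x, ...) {
  cat(sprintf("<brain_graph: %d nodes, %d edges, %s, tau = %s>\n",
              nrow(x$adjacency), x$n_edges_kept,
              if (x$weighted) "weighted" else "binary", format(x$tau)))
  invisible(x)
}

#' Binarize a brain graph
#'
#' Replaces every positive edge weight by 1; the edge set is unchanged.
#'
#' @param G A `brain_graph`.
#' @return A binary `brain_graph` with the same support.
#' @export
binarize <- function(G) {
  stopifnot(inherits(G, "brain_graph"))
  G$adjacency <- (G$adjacency > 0) * 1
  G$weighted <- FALSE
  G
}

#' Edge density of a brain graph
#'
#' Fraction of realized node pairs: `2 |E| / (q^2 - q)`.
#'
#' @param G A `brain_graph`.
#' @return Density in `[0, 1]`.
#' @export
edge_density <- function(G) {
  stopifnot(inherits(G, "brain_graph"))
  q <- nrow(G$adjacency)
  n_edges <- sum(G$adjacency[upper.tri(G$adjacency)] > 0)
  2 * n_edges / (q^2 - q)
}

#' Export a brain graph as GraphML
#'
#' Edge weights are written as the standard `weight` edge attribute.
#'
#' @param G A `brain_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(G, path) {
  stopifnot(inherits(G, "brain_graph"))
  g <- brain_graph_igraph(G, weighted = G$weighted)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# igraph view of a brain graph; binary graphs get no weight attribute
brain_graph_igraph <- function(G, weighted) {
  adj <- G$adjacency
  igraph::graph_from_adjacency_matrix(
    adj, mode = "undirected",
    weighted = if (weighted) TRUE else NULL, diag = FALSE)
}
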