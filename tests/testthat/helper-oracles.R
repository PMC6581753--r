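# Test helpers: graph fixtures and exhaustive-enumeration oracles for the
# local metrics. The oracles enumerate simple paths and triangles directly
# and are kept independent of the package implementation (no igraph).

# brain_graph fixture straight from an adjacency matrix
bg <- function(adj, weighted = TRUE, tau = 1) {
  adj <- as.matrix(adj)
  diag(adj) <- 0
  structure(list(adjacency = adj, weighted = weighted, tau = tau,
                 n_edges_kept = sum(adj[upper.tri(adj)] > 0),
                 node_labels = paste0("n", seq_len(nrow(adj)))),
            class = "brain_graph")
}

# random symmetric adjacency; continuous weights avoid shortest-path ties
rand_adj <- function(q, p = 0.5, weighted = FALSE) {
  A <- matrix(0, q, q)
  ut <- upper.tri(A)
  present <- stats::rbinom(sum(ut), 1, p)
  w <- if (weighted) stats::runif(sum(ut), 0.5, 3) else 1
  A[ut] <- present * w
  A + t(A)
}

# all simple paths between from and to; edge lengths from len matrix (Inf =
# no edge). Returns list(dist = min length, count = number of shortest
# paths, through = per-node counts of shortest paths passing through it).
oracle_path_info <- function(len, from, to, tol = 1e-9) {
  q <- nrow(len)
  paths <- list()
  walk <- function(node, visited, dist) {
    if (node == to) {
      paths[[length(paths) + 1L]] <<- list(path = visited, dist = dist)
      return(invisible())
    }
    for (nxt in seq_len(q)) {
      if (is.finite(len[node, nxt]) && !(nxt %in% visited))
        walk(nxt, c(visited, nxt), dist + len[node, nxt])
    }
  }
  walk(from, from, 0)
  if (length(paths) == 0L)
    return(list(dist = Inf, count = 0L, through = integer(q)))
  dists <- vapply(paths, `[[`, numeric(1), "dist")
  dmin <- min(dists)
  shortest <- paths[dists <= dmin + tol]
  through <- integer(q)
  for (p in shortest) {
    inner <- setdiff(p$path, c(from, to))
    through[inner] <- through[inner] + 1L
  }
  list(dist = dmin, count = length(shortest), through = through)
}

# edge lengths for shortest paths: 1/w on rescaled weights (or hops)
length_matrix <- function(adj, weighted) {
  w <- if (weighted && max(adj) > 0) adj / max(adj) else (adj > 0) * 1
  len <- matrix(Inf, nrow(adj), ncol(adj))
  len[w > 0] <- 1 / w[w > 0]
  len
}

oracle_degree <- function(adj, weighted) {
  if (weighted) rowSums(adj) else rowSums(adj > 0)
}

oracle_clustering <- function(adj, weighted) {
  q <- nrow(adj)
  a <- (adj > 0) * 1
  w <- if (weighted && max(adj) > 0) adj / max(adj) else a
  k <- rowSums(a)
  vals <- numeric(q)
  for (i in seq_len(q)) {
    if (k[i] < 2) next
    s <- 0
    for (j in seq_len(q)) for (h in seq_len(q)) {
      if (j != i && h != i && j != h)
        s <- s + (w[i, j] * w[j, h] * w[h, i])^(1 / 3)
    }
    vals[i] <- s / (k[i] * (k[i] - 1))  # ordered-pair sum = 2 * t_i
  }
  vals
}

oracle_efficiency <- function(adj, weighted) {
  q <- nrow(adj)
  a <- (adj > 0) * 1
  w <- if (weighted && max(adj) > 0) adj / max(adj) else a
  k <- rowSums(a)
  vals <- numeric(q)
  for (i in seq_len(q)) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) next
    sub <- adj[nb, nb, drop = FALSE]
    # restricted shortest paths live on the neighborhood subgraph, but
    # lengths still use weights rescaled by the whole-network maximum
    sub_w <- if (weighted && max(adj) > 0) sub / max(adj) else (sub > 0) * 1
    len <- matrix(Inf, length(nb), length(nb))
    len[sub_w > 0] <- 1 / sub_w[sub_w > 0]
    s <- 0
    for (jj in seq_along(nb)) for (hh in seq_along(nb)) {
      if (jj == hh) next
      d <- oracle_path_info(len, jj, hh)$dist
      if (is.finite(d))
        s <- s + (w[i, nb[jj]] * w[i, nb[hh]])^(1 / 3) / d
    }
    vals[i] <- s / (k[i] * (k[i] - 1))
  }
  vals
}

oracle_betweenness <- function(adj, weighted) {
  q <- nrow(adj)
  vals <- numeric(q)
  if (q < 3) return(vals)
  len <- length_matrix(adj, weighted)
  for (h in seq_len(q)) for (j in seq_len(q)) {
    if (h == j) next
    info <- oracle_path_info(len, h, j)
    if (info$count > 0) vals <- vals + info$through / info$count
  }
  vals / ((q - 1) * (q - 2))
}

# small deterministic cohort config for pipeline tests
tiny_config <- function(n_nodes = 20, n_subjects = 3L, n_sessions = 2L,
                        seed = 1L, subject_sd = 0.2, ...) {
  cohort_config(
    n_nodes = n_nodes,
    groups = data.frame(group = c("HC", "RR", "SP"),
                        n_subjects = n_subjects, n_sessions = n_sessions,
                        severity = c(0, 0.45, 1)),
    subject_sd = subject_sd, seed = seed, ...)
}
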