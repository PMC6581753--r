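#' Min-max normalization to [0, 1]
#'
#' `(v - min) / (max - min)`; a constant vector maps to all zeros so that
#' degenerate feature columns stay well-defined.
#'
#' @param v Finite numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(v) {
  if (anyNA(v) || any(!is.finite(v))) stop("input contains NA or non-finite values")
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(0, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Build the node-feature matrix for one experimental condition
#'
#' Assembles the q x d descriptor matrix X fed to the classifier:
#' * `identity` — the q x q identity matrix (the "featureless" condition:
#'   the model sees graph structure only); exempt from normalization.
#' * `D`, `BC`, `CC`, `E` — a single metric as a q x 1 column.
#' * `all-graphs` — q x 4 with columns `[D, BC, CC, E]`.
#'
#' Metric columns are min-max normalized per graph and per column, so every
#' sample is self-contained and no information leaks across the train/test
#' split; set `normalize = FALSE` to export raw metric values and apply a
#' cohort-level scheme externally.
#'
#' @param G A `brain_graph`.
#' @param condition One of `"identity"`, `"D"`, `"BC"`, `"CC"`, `"E"`,
#'   `"all-graphs"`.
#' @param weighted Use weighted metric variants.
#' @param normalize Min-max normalize metric columns (default TRUE).
#' @return A `node_feature_matrix`: numeric matrix with attributes
#'   `condition` and `d`.
#' @export
build_feature_matrix <- function(G, condition, weighted = FALSE,
                                 normalize = TRUE) {
  stopifnot(inherits(G, "brain_graph"))
  q <- nrow(G$adjacency)
  conditions <- c("identity", "D", "BC", "CC", "E", "all-graphs")
  if (!condition %in% conditions)
    stop(sprintf("unknown condition '%s'; expected one of %s", condition,
                 paste(conditions, collapse = ", ")))
  norm_col <- function(v) if (normalize) minmax_normalize(as.numeric(v)) else as.numeric(v)
  X <- switch(condition,
    "identity" = diag(q),
    "D" = cbind(D = norm_col(node_degree(G, weighted))),
    "BC" = cbind(BC = norm_col(betweenness_centrality(G, weighted))),
    "CC" = cbind(CC = norm_col(clustering_coefficient(G, weighted))),
    "E" = cbind(E = norm_col(local_efficiency(G, weighted))),
    "all-graphs" = {
      m <- all_local_metrics(G, weighted)
      cbind(D = norm_col(m$D), BC = norm_col(m$BC),
            CC = norm_col(m$CC), E = norm_col(m$E))
    })
  structure(X, condition = condition, d = ncol(X),
            class = c("node_feature_matrix", class(X)))
}
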