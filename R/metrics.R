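# Sparsification and graph metrics: characteristic path length, weighted
# clustering, communication capacity, degree centrality, per-network means.

#' Retain the top fraction of edge weights
#'
#' Ranks all `n(n-1)/2` upper-triangle weights in descending order (ties
#' broken deterministically by row then column index) and keeps the top
#' `ceiling(fraction * n(n-1)/2)` with their original weights; everything
#' else is zeroed and the matrix re-symmetrized. Retained cells whose weight
#' is exactly zero contribute no edge to the graph metrics.
#'
#' @param cm A `connectivity_matrix` (or plain symmetric matrix).
#' @param fraction Fraction of edges to retain, in (0, 1].
#' @param coords Optional region x 3 coordinate matrix (mm), needed later by
#'   [communication_capacity()].
#' @return An object of class `sparse_graph`: list with `weights`,
#'   `retained` (logical matrix), `retained_fraction`, `region_names`,
#'   `coords`.
#' @examples
#' W <- matrix(0, 5, 5); W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 0.5
#' sparsify_top_fraction(W, 0.10)  # keeps only the strongest of 10 pairs
#' @export
sparsify_top_fraction <- function(cm, fraction = 0.10, coords = NULL) {
  W <- if (inherits(cm, "connectivity_matrix")) cm$weights else as.matrix(cm)
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(W)
  if (is.null(rownames(W))) {
    rownames(W) <- colnames(W) <- sprintf("ROI_%03d", seq_len(n))
  }
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[ut]
  if (all(w == 0)) stop("all-zero matrix: no rankable edges", call. = FALSE)
  m <- ceiling(fraction * nrow(ut))
  keep <- order(-w, ut[, 1], ut[, 2])[seq_len(m)]
  retained <- matrix(FALSE, n, n)
  retained[ut[keep, , drop = FALSE]] <- TRUE
  retained <- retained | t(retained)
  Ws <- ifelse(retained, W, 0)
  diag(Ws) <- 0
  dimnames(Ws) <- dimnames(W)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3) {
      stop("`coords` must be an n x 3 matrix", call. = FALSE)
    }
  }
  structure(list(weights = Ws, retained = retained,
                 retained_fraction = fraction,
                 region_names = rownames(Ws), coords = coords),
            class = "sparse_graph")
}

#' @export
print.sparse_graph <- function(x, ...) {
  cat("Sparse graph:", length(x$region_names), "regions,",
      sum(x$retained[upper.tri(x$retained)]), "retained edge slots (fraction",
      x$retained_fraction, ")\n")
  invisible(x)
}

as_sparse_graph <- function(g) {
  if (!inherits(g, "sparse_graph")) {
    stop("expected a `sparse_graph` (see sparsify_top_fraction)", call. = FALSE)
  }
  g
}

# Shortest-path distance matrix with edge length = 1 / weight.
graph_distances <- function(g) {
  W <- g$weights
  ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  igraph::E(ig)$weight <- 1 / igraph::E(ig)$weight
  igraph::distances(ig, algorithm = "dijkstra")
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all ordered node pairs with a finite
#' distance, where edge length is the reciprocal of the connection weight
#' and distances come from Dijkstra's algorithm. The number of unreachable
#' ordered pairs is attached as attribute `n_unreachable`.
#'
#' @param g A `sparse_graph`.
#' @return The characteristic path length (scalar).
#' @export
char_path_length <- function(g) {
  g <- as_sparse_graph(g)
  n <- length(g$region_names)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  D <- graph_distances(g)
  off <- D[row(D) != col(D)]
  finite <- is.finite(off)
  if (!any(finite)) stop("no finite-distance node pair in the graph", call. = FALSE)
  structure(mean(off[finite]), n_unreachable = sum(!finite))
}

#' Weighted clustering coefficient
#'
#' Per node `i`: the sum over ordered neighbor pairs (j, k) of
#' `(w_ij * w_jk * w_ki)^(1/3)`, divided by `k_i (k_i - 1)` with `k_i` the
#' binary degree in the sparse graph; nodes with fewer than two neighbors
#' score 0. Raw weights are used exactly as retained (no max-weight
#' normalization), so values can exceed 1 when weights do. The global
#' coefficient is the mean over all nodes.
#'
#' @param g A `sparse_graph`.
#' @return List with `per_node` (named vector) and `global` (scalar mean).
#' @export
weighted_clustering <- function(g) {
  g <- as_sparse_graph(g)
  W <- g$weights
  A <- (W > 0) * 1
  k <- rowSums(A)
  W3 <- W^(1 / 3)
  numer <- diag(W3 %*% W3 %*% W3)
  cw <- ifelse(k >= 2, numer / (k * (k - 1)), 0)
  names(cw) <- g$region_names
  list(per_node = cw, global = mean(cw))
}

#' Communication capacity
#'
#' Per node: the sum over its retained edges of weight divided by the
#' Euclidean distance (mm) between the two region centroids — a
#' distance-discounted nodal strength quantifying information transfer
#' capability.
#'
#' @param g A `sparse_graph` carrying `coords`.
#' @return Named numeric vector (bits/mm).
#' @export
communication_capacity <- function(g) {
  g <- as_sparse_graph(g)
  if (is.null(g$coords)) {
    stop("communication capacity needs region coordinates ",
         "(pass `coords` to sparsify_top_fraction)", call. = FALSE)
  }
  D <- as.matrix(dist(g$coords))
  edges <- g$weights > 0
  zero_d <- edges & D == 0
  if (any(zero_d)) {
    ij <- which(zero_d, arr.ind = TRUE)[1, ]
    stop("connected regions ", g$region_names[ij[1]], " and ",
         g$region_names[ij[2]], " have identical coordinates", call. = FALSE)
  }
  ratio <- ifelse(edges, g$weights / D, 0)
  setNames(rowSums(ratio), g$region_names)
}

#' Degree centrality
#'
#' Binary degree in the sparse graph divided by `n - 1`.
#'
#' @param g A `sparse_graph`.
#' @return Named numeric vector in \[0, 1\].
#' @export
degree_centrality <- function(g) {
  g <- as_sparse_graph(g)
  n <- length(g$region_names)
  setNames(rowSums(g$weights > 0) / (n - 1), g$region_names)
}

#' Node metric table
#'
#' @param g A `sparse_graph` with coordinates.
#' @return Data frame with columns `region`, `comm_capacity`,
#'   `degree_centrality`, `clustering`.
#' @export
node_metrics <- function(g) {
  g <- as_sparse_graph(g)
  data.frame(region = g$region_names,
             comm_capacity = unname(communication_capacity(g)),
             degree_centrality = unname(degree_centrality(g)),
             clustering = unname(weighted_clustering(g)$per_node))
}

#' Per-network summary
#'
#' For every resting-state network: the mean shortest-path distance over
#' finite-distance pairs (i in the network, j outside it) and the mean
#' weighted clustering of its member nodes. A network with no members is
#' skipped with a warning; a network covering every node has no
#' between-network pairs and reports `NA` path length with a warning.
#'
#' @param g A `sparse_graph`.
#' @param metadata Node metadata with `region` and `network` columns.
#' @return Data frame with columns `network`, `n_nodes`,
#'   `mean_path_between`, `mean_clustering`.
#' @export
network_summary <- function(g, metadata) {
  g <- as_sparse_graph(g)
  if (!all(g$region_names %in% metadata$region)) {
    stop("metadata is missing regions present in the graph", call. = FALSE)
  }
  net <- metadata$network[match(g$region_names, metadata$region)]
  D <- graph_distances(g)
  cw <- weighted_clustering(g)$per_node
  nets <- unique(metadata$network)
  rows <- lapply(nets, function(nm) {
    members <- which(net == nm)
    if (length(members) == 0L) {
      warning("network ", nm, " has no member nodes; skipped", call. = FALSE)
      return(NULL)
    }
    others <- which(net != nm)
    mp <- if (length(others) == 0L) {
      warning("network ", nm, " covers all nodes; no between-network pairs",
              call. = FALSE)
      NA_real_
    } else {
      d <- D[members, others, drop = FALSE]
      d <- d[is.finite(d)]
      if (length(d) == 0L) NA_real_ else mean(d)
    }
    data.frame(network = nm, n_nodes = length(members),
               mean_path_between = mp, mean_clustering = mean(cw[members]))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
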