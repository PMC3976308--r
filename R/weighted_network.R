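#' Weighted network container
#'
#' A `weighted_network` is the coupling substrate of the Ising model: a
#' symmetric, non-negative, zero-diagonal weight matrix whose entries play the
#' role of anatomical connection densities. Optional per-node module labels
#' stand in for hemispheres.
#'
#' @param weights symmetric numeric n x n matrix, non-negative, zero diagonal.
#' @param node_labels optional character vector of length n.
#' @param module_labels optional integer vector of length n assigning each node
#'   to a module (e.g. hemisphere 1/2).
#'
#' @return An object of class `weighted_network`: a list with elements
#'   `n_nodes`, `weights`, `node_labels`, `module_labels`.
#' @export
weighted_network <- function(weights, node_labels = NULL, module_labels = NULL) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop("weights must be a square matrix")
  if (any(!is.finite(weights)))
    stop("weights must be finite")
  if (any(weights < 0))
    stop("weights must be non-negative")
  if (any(abs(diag(weights)) > 0))
    stop("weights must have a zero diagonal (no self-coupling)")
  if (max(abs(weights - t(weights))) > 1e-12 * max(1, max(abs(weights))))
    stop("weights must be symmetric")
  weights <- (weights + t(weights)) / 2  # remove rounding asymmetry
  if (!is.null(node_labels) && length(node_labels) != n)
    stop("node_labels length must equal number of nodes")
  if (!is.null(module_labels)) {
    if (length(module_labels) != n)
      stop("module_labels length must equal number of nodes")
    module_labels <- as.integer(module_labels)
  }
  structure(
    list(n_nodes = n, weights = unname(weights),
         node_labels = node_labels, module_labels = module_labels),
    class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  ne <- sum(x$weights > 0) / 2
  cat("<weighted_network> ", x$n_nodes, " nodes, ", ne, " edges",
      if (!is.null(x$module_labels))
        paste0(", ", length(unique(x$module_labels)), " modules"),
      "\n", sep = "")
  invisible(x)
}

#' Node strengths
#'
#' Strength of node i is the sum of the weights of its incident edges,
#' `sum_j A_ij`.
#'
#' @param net a [weighted_network()].
#' @return Numeric vector of length `n_nodes`.
#' @export
node_strength <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  rowSums(net$weights)
}

#' Edge list of a weighted network
#'
#' @param net a [weighted_network()].
#' @return A data.frame with 0-based columns `from`, `to` (`from < to`) and
#'   `weight`, one row per undirected edge.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  idx <- which(upper.tri(net$weights) & net$weights > 0, arr.ind = TRUE)
  data.frame(from = idx[, 1] - 1L, to = idx[, 2] - 1L,
             weight = net$weights[idx])
}

# internal: igraph view with inverse-weight distances available
as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

is_connected_net <- function(net) {
  igraph::is_connected(as_igraph(net))
}
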