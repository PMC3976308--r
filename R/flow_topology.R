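#' Per-node flow and topology statistics
#'
#' Tabulates, for each node: incoming flow (row sum of the flow matrix),
#' outgoing flow (column sum), their ratio `r = out / in` (the local
#' diminishing-marginal-returns indicator: `r > 1` marks a node whose
#' incoming channel is closer to saturation than its outgoing one, a
#' candidate information bottleneck), the mean inter-flip time `tau` when a
#' trajectory is supplied, and the structural metrics strength, local
#' efficiency and betweenness.
#'
#' Nodes with incoming flow below `eps` get `r = NA` (undefined sentinel);
#' their count is reported in the `n_undefined_r` attribute and they are
#' meant to be excluded from correlations.
#'
#' @param flow a [flow_matrix()].
#' @param net the [weighted_network()] substrate.
#' @param traj optional `spin_trajectory` for flip times.
#' @param eps incoming-flow threshold below which `r` is undefined.
#' @return A data.frame with one row per node: `node`, `strength`,
#'   `in_flow`, `out_flow`, `r`, `tau`, `local_efficiency`, `betweenness`.
#' @export
node_flow_stats <- function(flow, net, traj = NULL, eps = 1e-12) {
  n <- nrow(flow$flows)
  if (n != net$n_nodes) stop("flow and network dimensions differ")
  in_flow <- rowSums(flow$flows)
  out_flow <- colSums(flow$flows)
  r <- ifelse(in_flow < eps, NA_real_, out_flow / in_flow)
  gm <- graph_metrics(net)
  tau <- if (is.null(traj)) rep(NA_real_, n) else flip_times(traj)
  out <- data.frame(node = seq_len(n), strength = gm$strength,
                    in_flow = in_flow, out_flow = out_flow, r = r, tau = tau,
                    local_efficiency = gm$local_efficiency,
                    betweenness = gm$betweenness)
  attr(out, "n_undefined_r") <- sum(is.na(r))
  out
}

#' Global diminishing-marginal-returns ratio R
#'
#' `R = sd(outgoing flows) / sd(incoming flows)` over nodes, using the
#' population standard deviation. With symmetric interactions the flow
#' network would be symmetric and `R = 1`; `R > 1` signals that the incoming
#' distribution is sharper than the outgoing one — the global signature of
#' the law of diminishing marginal returns.
#'
#' @param flow a [flow_matrix()].
#' @return Scalar `R`, or `NA` (undefined sentinel) if `sd(in) < eps`.
#' @param eps degeneracy threshold on `sd(in)`.
#' @export
R_ratio <- function(flow, eps = 1e-12) {
  if (nrow(flow$flows) < 2) stop("need at least 2 nodes")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  sd_in <- pop_sd(rowSums(flow$flows))
  sd_out <- pop_sd(colSums(flow$flows))
  if (sd_in < eps) return(NA_real_)
  sd_out / sd_in
}

#' Intra- vs inter-module segregation of the flow network
#'
#' `S = (sum of flows within a module) / (sum of flows between modules)`.
#' With hemispheric labels this is the hemispheric segregation of the
#' information flow; it grows as lowering the temperature decouples the two
#' hemispheres.
#'
#' @param flow a [flow_matrix()].
#' @param module_labels integer module id per node (at least 2 distinct).
#' @return Scalar `S`; `+Inf` sentinel when the inter-module flow is zero.
#' @export
segregation <- function(flow, module_labels) {
  n <- nrow(flow$flows)
  if (length(module_labels) != n)
    stop("module_labels length must equal the number of nodes")
  if (length(unique(module_labels)) < 2)
    stop("need at least 2 modules to measure segregation")
  same <- outer(module_labels, module_labels, "==")
  intra <- sum(flow$flows[same])
  inter <- sum(flow$flows[!same])
  if (inter == 0) return(Inf)
  intra / inter
}

#' Binarize a flow matrix into an undirected graph
#'
#' An undirected edge `{i, j}` exists iff `max(flows[i, j], flows[j, i])`
#' exceeds the given quantile of the nonzero flow values. The max rule makes
#' the result invariant under transposition of the flow matrix, i.e.
#' identical for incoming- and outgoing-flow orientations.
#'
#' @param flow a [flow_matrix()].
#' @param binarize_quantile quantile of nonzero flows used as threshold.
#' @return Logical symmetric adjacency matrix.
#' @export
binarize_flow <- function(flow, binarize_quantile = 0.5) {
  F <- flow$flows
  sym <- pmax(F, t(F))
  nz <- F[flow$mask > 0]
  nz <- nz[nz > 0]
  thr <- if (length(nz) == 0) Inf else
    stats::quantile(nz, binarize_quantile, names = FALSE)
  adj <- sym > thr
  diag(adj) <- FALSE
  adj
}

#' Rich-club coefficient of the flow network
#'
#' On the binarized flow graph (see [binarize_flow()]),
#' `Phi(k) = 2 E_k / (N_k (N_k - 1))` where `N_k` is the number of nodes of
#' degree `k` or higher and `E_k` the number of edges among them: the
#' fraction of realized hub-to-hub links out of the possible ones. `Phi`
#' near 1 at criticality says the flow hubs are maximally interconnected.
#'
#' @param flow a [flow_matrix()], or a logical adjacency matrix already
#'   binarized.
#' @param binarize_quantile threshold quantile passed to [binarize_flow()].
#' @param k integer degree level(s); default all levels `1..max(degree)`.
#' @return Named numeric vector `Phi(k)`; `NA` sentinel where fewer than 2
#'   nodes qualify.
#' @export
rich_club <- function(flow, binarize_quantile = 0.5, k = NULL) {
  adj <- if (is.matrix(flow) && is.logical(flow)) flow
         else binarize_flow(flow, binarize_quantile)
  deg <- rowSums(adj)
  if (is.null(k)) k <- seq_len(max(1, max(deg)))
  phi <- vapply(k, function(kk) {
    keep <- deg >= kk
    nk <- sum(keep)
    if (nk < 2) return(NA_real_)
    ek <- sum(adj[keep, keep]) / 2
    2 * ek / (nk * (nk - 1))
  }, numeric(1))
  names(phi) <- k
  phi
}

#' Structural node metrics
#'
#' Strength (`sum_j A_ij`), local efficiency and betweenness on the weighted
#' substrate. Shortest-path lengths use the connectivity-toolbox convention
#' `distance = 1 / weight` on each edge. Local efficiency of node i is the
#' mean over pairs of its neighbours of `1 / d(u, v)` computed inside the
#' subgraph induced by the neighbours (0 when i has fewer than 2
#' neighbours). Betweenness is the endpoint-exclusive shortest-path
#' betweenness with even splitting over ties, normalised to the fraction of
#' the `(n-1)(n-2)/2` source-target pairs.
#'
#' @param net a [weighted_network()]; a warning is issued when disconnected
#'   (metrics then apply per component, unreachable pairs contribute 0
#'   efficiency).
#' @return A data.frame with `node`, `strength`, `local_efficiency`,
#'   `betweenness`.
#' @export
graph_metrics <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  g <- as_igraph(net)
  if (!igraph::is_connected(g))
    warning("network is disconnected; metrics computed per component")
  n <- net$n_nodes
  inv_w <- 1 / igraph::E(g)$weight
  btw <- igraph::betweenness(g, weights = inv_w, directed = FALSE)
  denom <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  leff <- vapply(seq_len(n), function(i) {
    nb <- as.integer(igraph::neighbors(g, i))
    if (length(nb) < 2) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    d <- igraph::distances(sub, weights = 1 / igraph::E(sub)$weight)
    iu <- upper.tri(d)
    mean(ifelse(is.finite(d[iu]), 1 / d[iu], 0))
  }, numeric(1))
  data.frame(node = seq_len(n), strength = node_strength(net),
             local_efficiency = leff, betweenness = btw / denom)
}

#' Pearson correlation over nodes with sentinel exclusion
#'
#' Standard product-moment correlation computed on the pairs where both
#' values are finite (undefined sentinels `NA`/`Inf` excluded), reporting
#' how many pairs were used.
#'
#' @param x,y numeric vectors of equal length (per-node values).
#' @return List with `r` (the coefficient, `NA` sentinel if fewer than 3
#'   finite pairs remain) and `n` (finite pairs used).
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) return(list(r = NA_real_, n = n))
  list(r = stats::cor(x[ok], y[ok]), n = n)
}
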