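#' Square-lattice substrate
#'
#' Builds an `L x L` square lattice with unit coupling weights on
#' nearest-neighbour bonds, the classical finite-size testbed whose
#' pseudo-critical inverse temperature approaches the Onsager value
#' `log(1 + sqrt(2)) / 2` from above as `L` grows.
#'
#' @param L side length (nodes per side), `L >= 2`.
#' @param periodic wrap the boundary (torus) if `TRUE`.
#' @return A [weighted_network()] with `L^2` nodes.
#' @examples
#' net <- make_lattice2d(4, periodic = TRUE)
#' table(rowSums(net$weights > 0))  # every node has degree 4
#' @export
make_lattice2d <- function(L, periodic = TRUE) {
  L <- as.integer(L)
  if (is.na(L) || L < 2) stop("L must be an integer >= 2")
  n <- L * L
  id <- function(r, c) (r - 1L) * L + c  # row-major, 1-based
  W <- matrix(0, n, n)
  for (r in seq_len(L)) {
    for (c in seq_len(L)) {
      i <- id(r, c)
      if (c < L) W[i, id(r, c + 1L)] <- 1
      else if (periodic && L > 2L) W[i, id(r, 1L)] <- 1
      if (r < L) W[i, id(r + 1L, c)] <- 1
      else if (periodic && L > 2L) W[i, id(1L, c)] <- 1
    }
  }
  if (periodic && L == 2L) {
    # torus of side 2 degenerates to doubled bonds; keep simple unit bonds
    W[id(1, 1), id(1, 2)] <- 1; W[id(1, 1), id(2, 1)] <- 1
    W[id(2, 2), id(1, 2)] <- 1; W[id(2, 2), id(2, 1)] <- 1
  }
  weighted_network(pmax(W, t(W)))
}

#' Deterministic scale-free network
#'
#' Hierarchical deterministic scale-free graph built recursively: generation
#' `g` is three copies of generation `g - 1`; the root of the middle copy
#' becomes the new root and is joined by unit-weight edges to the bottom-level
#' (leaf) nodes of the two outer copies. Generation 4 has `3^4 = 81` nodes.
#'
#' @param generations number of recursive steps, `>= 0`.
#' @return A [weighted_network()] with `3^generations` nodes; node 1 is the
#'   root.
#' @export
make_deterministic_scale_free <- function(generations) {
  g <- as.integer(generations)
  if (is.na(g) || g < 0) stop("generations must be a non-negative integer")
  # state: edge list (1-based), root id, bottom-node ids
  edges <- matrix(integer(0), ncol = 2)
  root <- 1L
  bottom <- 1L
  n <- 1L
  for (k in seq_len(g)) {
    # copies at offsets 0 (left), n (middle), 2n (right); new root = middle root
    e3 <- rbind(edges, edges + n, edges + 2L * n)
    new_root <- root + n
    leaves <- c(bottom, bottom + 2L * n)  # bottom nodes of the two outer copies
    e3 <- rbind(e3, cbind(rep(new_root, length(leaves)), leaves))
    edges <- e3
    # the bottom level of the new graph: leaves of the two outer copies
    bottom <- c(bottom, bottom + 2L * n)
    root <- new_root
    n <- 3L * n
  }
  W <- matrix(0, n, n)
  if (nrow(edges) > 0) {
    W[edges] <- 1
    W[edges[, 2:1, drop = FALSE]] <- 1
  }
  # put the root first so node 1 is always the hub
  perm <- c(root, setdiff(seq_len(n), root))
  weighted_network(W[perm, perm, drop = FALSE])
}

#' Surrogate two-hemisphere connectome
#'
#' Random weighted substrate emulating the gross organisation of a structural
#' brain network: two (or more) modules of equal size with dense intra-module
#' and sparse inter-module wiring, and log-normally distributed positive
#' weights giving a heterogeneous, fat-tailed strength distribution. It is a
#' synthetic stand-in, not a measured connectome.
#'
#' @param n_nodes number of nodes.
#' @param n_modules number of modules (hemisphere proxies), `>= 1`.
#' @param intra_density edge probability within a module, in `[0, 1]`.
#' @param inter_density edge probability between modules, in `[0, 1]`.
#' @param weight_scale median edge weight (log-normal `exp(meanlog)`).
#' @param weight_sigma log-normal `sdlog` controlling weight heterogeneity.
#' @param seed integer RNG seed; identical seeds give identical networks.
#' @param max_retries resampling budget used to reach a connected graph.
#' @return A connected [weighted_network()] with `module_labels` populated.
#' @export
make_surrogate_connectome <- function(n_nodes = 66, n_modules = 2,
                                      intra_density = 0.30,
                                      inter_density = 0.05,
                                      weight_scale = 0.3, weight_sigma = 1.0,
                                      seed = 1L, max_retries = 100L) {
  if (n_modules < 1 || n_modules > n_nodes)
    stop("need 1 <= n_modules <= n_nodes")
  if (intra_density < 0 || intra_density > 1 ||
      inter_density < 0 || inter_density > 1)
    stop("densities must lie in [0, 1]")
  modules <- rep(seq_len(n_modules), length.out = n_nodes)
  modules <- sort(modules)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  for (try in seq_len(max_retries)) {
    same <- outer(modules, modules, "==")
    p <- ifelse(same, intra_density, inter_density)
    up <- upper.tri(p)
    edge <- matrix(FALSE, n_nodes, n_nodes)
    edge[up] <- stats::runif(sum(up)) < p[up]
    W <- matrix(0, n_nodes, n_nodes)
    nw <- sum(edge)
    W[edge] <- stats::rlnorm(nw, meanlog = log(weight_scale),
                             sdlog = weight_sigma)
    W <- W + t(W)
    net <- weighted_network(W, module_labels = modules)
    # inter_density = 0 asks for deliberately disconnected hemispheres:
    # require each module connected instead of the whole graph
    ok <- if (inter_density == 0) {
      all(vapply(unique(modules), function(mm) {
        sub <- weighted_network(W[modules == mm, modules == mm, drop = FALSE])
        sub$n_nodes == 1 || is_connected_net(sub)
      }, logical(1)))
    } else {
      is_connected_net(net)
    }
    if (ok) return(net)
  }
  stop("could not generate a connected surrogate within the retry budget; ",
       "increase densities or max_retries")
}

#' Degree-preserving shuffle null model
#'
#' Rewires the binary backbone of a network by repeated double-edge swaps
#' (preserving every node's degree exactly) and then reassigns the original
#' multiset of edge weights onto the rewired edges by random permutation.
#' This is the null used to ask whether a result depends on the specific
#' wiring and weight placement beyond the degree sequence.
#'
#' @param net a [weighted_network()] with at least 2 edges.
#' @param seed integer RNG seed.
#' @param n_attempts number of attempted swaps; default `10 * n_edges`.
#' @return A [weighted_network()] with the same degree sequence and weight
#'   multiset. If no valid swap exists the input is returned with a warning.
#' @export
degree_preserving_shuffle <- function(net, seed = 1L, n_attempts = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  el <- network_edges(net)
  ne <- nrow(el)
  if (ne < 2) stop("need at least 2 edges to shuffle")
  if (is.null(n_attempts)) n_attempts <- 10L * ne
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  a <- el$from + 1L
  b <- el$to + 1L
  n <- net$n_nodes
  adj <- matrix(FALSE, n, n)
  adj[cbind(a, b)] <- TRUE
  adj[cbind(b, a)] <- TRUE
  n_success <- 0L
  for (it in seq_len(n_attempts)) {
    pick <- sample.int(ne, 2L)
    e1 <- pick[1]; e2 <- pick[2]
    u <- a[e1]; v <- b[e1]; x <- a[e2]; y <- b[e2]
    # swap to (u,x),(v,y) or (u,y),(v,x) with equal probability
    if (stats::runif(1) < 0.5) { tmp <- x; x <- y; y <- tmp }
    if (u == x || u == y || v == x || v == y) next
    if (adj[u, x] || adj[v, y]) next
    adj[u, v] <- adj[v, u] <- FALSE
    adj[x, y] <- adj[y, x] <- FALSE
    adj[u, x] <- adj[x, u] <- TRUE
    adj[v, y] <- adj[y, v] <- TRUE
    a[e1] <- min(u, x); b[e1] <- max(u, x)
    a[e2] <- min(v, y); b[e2] <- max(v, y)
    n_success <- n_success + 1L
  }
  if (n_success == 0L) {
    warning("no valid double-edge swap found; returning the input unchanged")
    return(net)
  }
  wperm <- sample(el$weight)
  W <- matrix(0, n, n)
  W[cbind(a, b)] <- wperm
  W[cbind(b, a)] <- wperm
  weighted_network(W, node_labels = net$node_labels,
                   module_labels = net$module_labels)
}

# save/restore .Random.seed so generator seeding does not clobber the
# caller's RNG stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}
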