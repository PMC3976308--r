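# Independent brute-force oracles used to verify the package implementations.
# These deliberately avoid the package's own code paths: states are enumerated
# with expand.grid, distances by exhaustive simple-path search, etc.

# all 2^n spin configurations as rows of a matrix (entries -1/+1)
all_states <- function(n) {
  as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
}

# exact Boltzmann distribution over configurations for energy
# E(s) = -sum_{i<j} A_ij s_i s_j
boltzmann_probs <- function(W, beta) {
  st <- all_states(nrow(W))
  E <- apply(st, 1, function(s) -0.5 * sum(W * outer(s, s)))
  w <- exp(-beta * E)
  list(states = st, E = E, p = w / sum(w))
}

# exact one-sweep transition matrix for random-site Glauber updates:
# single-update kernel averaged over sites, raised to the n-th power
glauber_sweep_matrix <- function(W, beta) {
  n <- nrow(W)
  st <- all_states(n)
  ns <- nrow(st)
  P <- matrix(0, ns, ns)
  key <- function(s) paste(s, collapse = ",")
  row_of <- structure(seq_len(ns), names = apply(st, 1, key))
  for (q in seq_len(ns)) {
    s <- st[q, ]
    for (i in seq_len(n)) {
      h <- sum(W[i, ] * s)
      pf <- 1 / (1 + exp(beta * 2 * s[i] * h))
      sf <- s
      sf[i] <- -sf[i]
      P[q, row_of[[key(sf)]]] <- P[q, row_of[[key(sf)]]] + pf / n
      P[q, q] <- P[q, q] + (1 - pf) / n
    }
  }
  out <- diag(ns)
  for (k in seq_len(n)) out <- out %*% P
  list(states = st, P1 = P, Psweep = out)
}

# stationary distribution of a stochastic matrix by power iteration
stationary_dist <- function(P, iters = 20000, tol = 1e-14) {
  p <- rep(1 / nrow(P), nrow(P))
  for (k in seq_len(iters)) {
    p2 <- as.vector(p %*% P)
    if (max(abs(p2 - p)) < tol) return(p2 / sum(p2))
    p <- p2
  }
  p / sum(p)
}

# batch-means standard error for an autocorrelated scalar series
batch_se <- function(x, n_batches = 20) {
  bs <- floor(length(x) / n_batches)
  means <- vapply(seq_len(n_batches), function(b)
    mean(x[((b - 1) * bs + 1):(b * bs)]), numeric(1))
  stats::sd(means) / sqrt(n_batches)
}

# sample skewness (m3 / m2^{3/2})
skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}

# exhaustive shortest paths with edge length 1/weight: enumerate every simple
# path between each pair (feasible for n <= 6); returns the distance matrix,
# the count of shortest paths per pair, and the count through each interior
# node
brute_paths <- function(W) {
  n <- nrow(W)
  dmat <- matrix(Inf, n, n)
  diag(dmat) <- 0
  nshort <- matrix(0, n, n)
  through <- array(0, dim = c(n, n, n))  # [source, target, interior]
  paths_from <- function(path, target, len) {
    i <- path[length(path)]
    if (i == target) return(list(list(path = path, len = len)))
    out <- list()
    for (j in seq_len(n)) {
      if (W[i, j] > 0 && !(j %in% path))
        out <- c(out, paths_from(c(path, j), target, len + 1 / W[i, j]))
    }
    out
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    ps <- paths_from(s, t, 0)
    if (length(ps) == 0) next
    lens <- vapply(ps, function(p) p$len, numeric(1))
    dmat[s, t] <- min(lens)
    best <- which(abs(lens - dmat[s, t]) < 1e-12)
    nshort[s, t] <- length(best)
    for (b in best) {
      interior <- setdiff(ps[[b]]$path, c(s, t))
      for (v in interior) through[s, t, v] <- through[s, t, v] + 1
    }
  }
  list(d = dmat, nshort = nshort, through = through)
}

# brute-force node metrics from brute_paths: betweenness as the tie-split
# fraction of shortest paths through the node, local efficiency from the
# neighbour-induced subgraph
brute_graph_metrics <- function(W) {
  n <- nrow(W)
  bp <- brute_paths(W)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (bp$nshort[s, t] > 0)
        tot <- tot + bp$through[s, t, v] / bp$nshort[s, t]
    }
    btw[v] <- tot / (if (n > 2) (n - 1) * (n - 2) / 2 else 1)
  }
  leff <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(W[v, ] > 0)
    if (length(nb) < 2) { leff[v] <- 0; next }
    sub <- W[nb, nb, drop = FALSE]
    d <- brute_paths(sub)$d
    iu <- upper.tri(d)
    leff[v] <- mean(ifelse(is.finite(d[iu]), 1 / d[iu], 0))
  }
  list(strength = rowSums(W), local_efficiency = leff, betweenness = btw)
}

# exhaustive rich-club count on a logical adjacency matrix
brute_rich_club <- function(adj, k) {
  deg <- rowSums(adj)
  keep <- which(deg >= k)
  if (length(keep) < 2) return(NA_real_)
  e <- 0
  for (a in keep) for (b in keep) if (a < b && adj[a, b]) e <- e + 1
  2 * e / (length(keep) * (length(keep) - 1))
}

# small fixed fixtures
pair_net <- function(w = 1) weighted_network(matrix(c(0, w, w, 0), 2))
chain3_net <- function() weighted_network(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3))

# wrap a raw +-1 matrix as a trajectory (for estimator tests on constructed
# series)
fake_traj <- function(spins, beta = 0) {
  structure(list(spins = spins, beta = beta, dynamics = "constructed",
                 n_transient = 0L, seed = NA_integer_),
            class = "spin_trajectory")
}
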