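#' Joint transition counts for one ordered spin pair
#'
#' Counts of the joint state `(target_next, target_past_block,
#' source_past_block)` over the recorded trajectory, the sufficient statistic
#' of the plug-in transfer-entropy estimator. Past blocks cover `m` recorded
#' steps; the counts sum to `T - m`.
#'
#' @param traj a `spin_trajectory`.
#' @param source,target 1-based node indices, `source != target`.
#' @param m embedding (past-block) length in recorded steps.
#' @return A `transition_counts` object: numeric array of length
#'   `2^(2m + 1)` with attributes `m` and `dim` `(2, 2^m, 2^m)` ordered as
#'   (next target bit, target block, source block).
#' @export
transition_counts <- function(traj, source, target, m = 1L) {
  if (source == target) stop("source and target must differ")
  m <- as.integer(m)
  if (m < 1) stop("m must be >= 1")
  S <- traj$spins
  if (nrow(S) - m < 1) stop("trajectory too short for embedding length m")
  counts <- cpp_te_counts(S[, target], S[, source], m)
  structure(counts, m = m, dim = c(2L, 2L^m, 2L^m),
            class = "transition_counts")
}

#' Plug-in bivariate transfer entropy for one ordered pair
#'
#' `TE(source -> target) = sum p(a, b, c) log2[ p(a | b, c) / p(a | b) ]`
#' where `a` is the target's next state and `b`, `c` are the `m`-step past
#' blocks of target and source. Probabilities are empirical frequencies
#' (maximum likelihood, no smoothing); states never observed contribute
#' zero; the result is clamped at 0, since negative raw values can only come
#' from floating-point rounding.
#'
#' @inheritParams transition_counts
#' @return TE in bits (non-negative scalar).
#' @export
transfer_entropy_pair <- function(traj, source, target, m = 1L) {
  counts <- transition_counts(traj, source, target, m)
  if (sum(counts) < 100)
    warning("fewer than 100 transitions; TE estimate will be strongly biased")
  te_from_transition_counts(counts)
}

#' Transfer entropy from transition counts
#'
#' @param counts a `transition_counts` object (or the equivalent array with
#'   an `m` attribute).
#' @return TE in bits.
#' @export
te_from_transition_counts <- function(counts) {
  m <- attr(counts, "m")
  cpp_te_from_counts(as.numeric(counts), as.integer(m))
}

#' Block-bootstrap standard error of a TE estimate
#'
#' Resamples the stream of transition tuples in contiguous blocks (to respect
#' the autocorrelation of the sweep-sampled chain) and recomputes the plug-in
#' TE on each replicate.
#'
#' @inheritParams transition_counts
#' @param n_boot number of bootstrap replicates.
#' @param block_length block size in recorded steps.
#' @return Standard deviation of the bootstrap replicates (bits).
#' @export
te_bootstrap_se <- function(traj, source, target, m = 1L, n_boot = 100L,
                            block_length = 100L) {
  S <- traj$spins
  T_ <- nrow(S)
  nt <- T_ - m  # number of transition tuples
  # per-tuple joint-state index, so each replicate is a single tabulate()
  a <- (S[(m + 1):T_, target] > 0) + 0L
  b <- integer(nt); cc <- integer(nt)
  for (k in seq_len(m)) {
    b <- b + ((S[(m + 1 - k):(T_ - k), target] > 0) + 0L) * 2L^(k - 1L)
    cc <- cc + ((S[(m + 1 - k):(T_ - k), source] > 0) + 0L) * 2L^(k - 1L)
  }
  idx <- 1L + a + 2L * b + as.integer(2L^(m + 1)) * cc
  nbins <- as.integer(2L^(2L * m + 1L))
  n_blocks <- ceiling(nt / block_length)
  reps <- vapply(seq_len(n_boot), function(r) {
    starts <- sample.int(nt - block_length + 1L, n_blocks, replace = TRUE)
    take <- as.vector(outer(0:(block_length - 1L), starts, "+"))[seq_len(nt)]
    cpp_te_from_counts(as.numeric(tabulate(idx[take], nbins)), m)
  }, numeric(1))
  stats::sd(reps)
}

#' Directed information-flow matrix on the structural links
#'
#' Computes the chosen pairwise estimator for every ordered pair of spins
#' joined by a structural link, and zero elsewhere: flows between unlinked
#' spins are not estimated (bivariate flow on the coupling support). The flow
#' `source -> target` is stored at `flows[target, source]`, so row sums are
#' incoming and column sums outgoing flow.
#'
#' @param traj a `spin_trajectory` simulated on `net`.
#' @param net the [weighted_network()] substrate.
#' @param estimator `"te"` (plug-in transfer entropy, bits) or `"granger"`
#'   (linear Granger index).
#' @param m embedding length.
#' @return A `flow_matrix` object: list with `flows` (n x n), `mask`
#'   (structural-link indicator), `estimator`, `m`, `beta`, `dynamics`.
#' @export
flow_matrix <- function(traj, net, estimator = c("te", "granger"), m = 1L) {
  estimator <- match.arg(estimator)
  S <- traj$spins
  n <- net$n_nodes
  if (ncol(S) != n) stop("trajectory and network dimensions differ")
  mask <- (net$weights > 0) * 1L
  diag(mask) <- 0L
  F <- matrix(0, n, n)
  idx <- which(mask > 0, arr.ind = TRUE)  # [target, source] slots
  if (nrow(idx) > 0) {
    if (estimator == "te") {
      pairs <- cbind(idx[, 2] - 1L, idx[, 1] - 1L)  # (source, target) 0-based
      F[idx] <- cpp_flow_te(S, pairs, as.integer(m))
    } else {
      for (r in seq_len(nrow(idx)))
        F[idx[r, 1], idx[r, 2]] <- granger_pair(traj, source = idx[r, 2],
                                                target = idx[r, 1], m = m)
    }
  }
  structure(
    list(flows = F, mask = mask, estimator = estimator, m = as.integer(m),
         beta = traj$beta, dynamics = traj$dynamics),
    class = "flow_matrix")
}

#' @export
print.flow_matrix <- function(x, ...) {
  cat("<flow_matrix> ", nrow(x$flows), " nodes, estimator ", x$estimator,
      ", m = ", x$m, ", beta = ", x$beta, ", total flow ",
      signif(total_flow(x), 4), "\n", sep = "")
  invisible(x)
}

#' Total information flow
#'
#' Sum of the pairwise flows over all linked ordered pairs.
#'
#' @param flow a [flow_matrix()].
#' @return Scalar (bits for the TE estimator).
#' @export
total_flow <- function(flow) {
  sum(flow$flows)
}

#' Linear Granger index for one ordered pair
#'
#' The spins are treated as real-valued ±1 series. The index is
#' `delta(source -> target) = log2( e_restricted / e_full )`, the log-ratio
#' of least-squares residual variances of predicting the target's next value
#' from its own `m`-step past (restricted) versus its own and the source's
#' past (full), both with intercept. Variances are floored at `1e-12` before
#' the ratio. Base-2 logarithm, matching the transfer-entropy unit, so that
#' the Gaussian-approximation relation `TE ≈ delta / 2` holds in bits.
#'
#' @inheritParams transition_counts
#' @return Non-negative scalar index (bits scale).
#' @export
granger_pair <- function(traj, source, target, m = 1L) {
  if (source == target) stop("source and target must differ")
  S <- traj$spins
  T_ <- nrow(S)
  y <- S[(m + 1):T_, target]
  if (stats::var(y) == 0) {
    warning("constant target series; Granger index set to 0")
    return(0)
  }
  Xr <- matrix(1, T_ - m, 1L + m)
  Xf <- matrix(1, T_ - m, 1L + 2L * m)
  for (k in seq_len(m)) {
    Xr[, 1L + k] <- S[(m + 1 - k):(T_ - k), target]
    Xf[, 1L + k] <- S[(m + 1 - k):(T_ - k), target]
    Xf[, 1L + m + k] <- S[(m + 1 - k):(T_ - k), source]
  }
  rss <- function(X) {
    fit <- stats::lm.fit(X, y)
    mean(fit$residuals^2)
  }
  er <- max(rss(Xr), 1e-12)
  ef <- max(rss(Xf), 1e-12)
  max(log2(er / ef), 0)
}

#' Exact transfer entropy for tiny systems by enumeration
#'
#' Independent verification oracle for the plug-in estimator: for a network
#' of at most 4 spins under random-site Glauber updates with per-sweep
#' sampling, builds the exact `2^N x 2^N` single-update transition matrix,
#' takes its `N`-th power (one sweep), solves for the stationary
#' distribution, marginalises the exact one-step joint
#' `p(target_next, target, source)` and evaluates the transfer entropy in
#' closed form.
#'
#' @param net a [weighted_network()] with `n_nodes <= 4`.
#' @param beta inverse temperature.
#' @param source,target 1-based node indices.
#' @return Exact TE in bits for embedding `m = 1`.
#' @export
exact_te_oracle <- function(net, beta, source, target) {
  n <- net$n_nodes
  if (n > 4) stop("oracle enumeration limited to n_nodes <= 4")
  if (source == target) stop("source and target must differ")
  ns <- 2L^n
  # state q in 0..2^n-1; bit i (1-based node) = (s_i + 1)/2
  spin_of <- function(q, i) 2 * bitwAnd(bitwShiftR(q, i - 1L), 1L) - 1
  states <- matrix(0, ns, n)
  for (i in seq_len(n)) states[, i] <- spin_of(0:(ns - 1L), i)
  P1 <- matrix(0, ns, ns)
  for (q in 0:(ns - 1L)) {
    s <- states[q + 1L, ]
    stay <- 0
    for (i in seq_len(n)) {
      h <- sum(net$weights[i, ] * s)
      dE <- 2 * s[i] * h
      p_flip <- 1 / (1 + exp(beta * dE))
      qf <- bitwXor(q, bitwShiftL(1L, i - 1L))
      P1[q + 1L, qf + 1L] <- P1[q + 1L, qf + 1L] + p_flip / n
      stay <- stay + (1 - p_flip) / n
    }
    P1[q + 1L, q + 1L] <- P1[q + 1L, q + 1L] + stay
  }
  Psweep <- P1
  if (n > 1) for (k in seq_len(n - 1L)) Psweep <- Psweep %*% P1
  # stationary distribution: left eigenvector of Psweep for eigenvalue 1
  ev <- eigen(t(Psweep))
  k1 <- which.min(abs(ev$values - 1))
  pi_s <- Re(ev$vectors[, k1])
  pi_s <- pi_s / sum(pi_s)
  joint2 <- pi_s * Psweep  # p(state, state')
  # marginalise to (a = target', b = target, c = source)
  p <- array(0, dim = c(2, 2, 2))
  bit <- function(q, i) bitwAnd(bitwShiftR(q, i - 1L), 1L)
  for (q in 0:(ns - 1L)) for (qp in 0:(ns - 1L)) {
    a <- bit(qp, target) + 1L
    b <- bit(q, target) + 1L
    cc <- bit(q, source) + 1L
    p[a, b, cc] <- p[a, b, cc] + joint2[q + 1L, qp + 1L]
  }
  p_bc <- apply(p, c(2, 3), sum)
  p_ab <- apply(p, c(1, 2), sum)
  p_b <- apply(p, 2, sum)
  te <- 0
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    x <- p[a, b, cc]
    if (x > 0)
      te <- te + x * log2((x * p_b[b]) / (p_ab[a, b] * p_bc[b, cc]))
  }
  max(te, 0)
}
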