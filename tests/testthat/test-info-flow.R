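test_that("TE vanishes for independent series and is 1 bit for a copied one", {
  set.seed(31)
  T_ <- 1e5
  ind <- fake_traj(cbind(sample(c(-1L, 1L), T_, TRUE),
                         sample(c(-1L, 1L), T_, TRUE)))
  expect_lt(transfer_entropy_pair(ind, 1, 2), 5e-4)
  expect_lt(transfer_entropy_pair(ind, 2, 1), 5e-4)

  src <- sample(c(-1L, 1L), T_, TRUE)
  tgt <- c(1L, src[-T_])  # s_i(t+1) = s_j(t)
  cp <- fake_traj(cbind(src, tgt))
  expect_lt(abs(transfer_entropy_pair(cp, 1, 2) - 1), 0.01)
  expect_error(transfer_entropy_pair(ind, 2, 2), "must differ")
})

test_that("transition counts sum to T - m and reproduce the pair TE", {
  net <- chain3_net()
  tr <- simulate_ising(net, 0.5, n_sweeps = 2000, n_transient = 100, seed = 2)
  for (m in 1:2) {
    ct <- transition_counts(tr, source = 1, target = 2, m = m)
    expect_equal(sum(ct), 2000 - m)
    expect_true(all(ct >= 0))
    expect_equal(te_from_transition_counts(ct),
                 transfer_entropy_pair(tr, 1, 2, m = m))
  }
})

test_that("plug-in TE agrees with the enumeration oracle on the chain", {
  net <- chain3_net()
  tr <- simulate_ising(net, 0.5, n_sweeps = 1e5, n_transient = 5000, seed = 8)
  for (pair in list(c(1, 2), c(2, 1), c(2, 3), c(3, 2))) {
    te <- transfer_entropy_pair(tr, pair[1], pair[2])
    or <- exact_te_oracle(net, 0.5, pair[1], pair[2])
    se <- te_bootstrap_se(tr, pair[1], pair[2])
    expect_lt(abs(te - or), 3 * se)
  }
})

test_that("exact oracle: zero at beta 0, zero for uncoupled pairs, matches a hand enumeration", {
  net <- chain3_net()
  for (pair in list(c(1, 2), c(2, 3), c(1, 3)))
    expect_equal(exact_te_oracle(net, 0, pair[1], pair[2]), 0)

  # one isolated spin: no information flows to or from it
  one_edge <- weighted_network(matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3))
  expect_lt(exact_te_oracle(one_edge, 0.7, 3, 1), 1e-12)
  expect_lt(exact_te_oracle(one_edge, 0.7, 1, 3), 1e-12)

  # independent second implementation (expand.grid state space, power
  # iteration for the stationary law) must agree to 12 decimals
  net2 <- pair_net()
  beta <- 0.5
  or <- glauber_sweep_matrix(net2$weights, beta)
  pi_s <- stationary_dist(or$Psweep)
  joint <- pi_s * or$Psweep
  p <- array(0, dim = c(2, 2, 2))
  for (q in 1:4) for (qp in 1:4) {
    a <- (or$states[qp, 1] + 1) / 2 + 1
    b <- (or$states[q, 1] + 1) / 2 + 1
    cc <- (or$states[q, 2] + 1) / 2 + 1
    p[a, b, cc] <- p[a, b, cc] + joint[q, qp]
  }
  te_hand <- 0
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    pa_bc <- p[a, b, cc] / sum(p[, b, cc])
    pa_b <- sum(p[a, b, ]) / sum(p[, b, ])
    if (p[a, b, cc] > 0)
      te_hand <- te_hand + p[a, b, cc] * log2(pa_bc / pa_b)
  }
  expect_equal(exact_te_oracle(net2, beta, 2, 1), te_hand, tolerance = 1e-12)
  expect_error(exact_te_oracle(make_lattice2d(3), 0.5, 1, 2), "<= 4")
})

test_that("flow matrix respects the structural mask and sums to the total", {
  empty <- weighted_network(matrix(0, 4, 4))
  tr <- fake_traj(matrix(sample(c(-1L, 1L), 4 * 500, TRUE), 500, 4))
  fl <- flow_matrix(tr, empty, "te")
  expect_true(all(fl$flows == 0))

  net <- make_surrogate_connectome(12, seed = 3)
  tr0 <- simulate_ising(net, 0, n_sweeps = 1e5, n_transient = 100, seed = 5)
  fl0 <- flow_matrix(tr0, net, "te")
  expect_true(all(fl0$flows[fl0$mask == 0] == 0))
  expect_true(all(fl0$flows[fl0$mask > 0] < 5e-4))
  expect_equal(total_flow(fl0), sum(fl0$flows))
  expect_error(flow_matrix(tr0, net, "mutual_information"), "arg")

  # the batched C++ path must equal the per-pair estimator
  tr1 <- simulate_ising(net, 0.3, n_sweeps = 3000, n_transient = 500, seed = 6)
  fl1 <- flow_matrix(tr1, net, "te")
  idx <- which(fl1$mask > 0, arr.ind = TRUE)
  for (r in sample(nrow(idx), 5)) {
    expect_equal(fl1$flows[idx[r, 1], idx[r, 2]],
                 transfer_entropy_pair(tr1, idx[r, 2], idx[r, 1]))
  }
})

test_that("Granger index: independence, near-deterministic driving, TE relation", {
  set.seed(41)
  T_ <- 1e5
  ind <- fake_traj(cbind(sample(c(-1L, 1L), T_, TRUE),
                         sample(c(-1L, 1L), T_, TRUE)))
  expect_lt(granger_pair(ind, 1, 2), 1e-3)

  src <- sample(c(-1L, 1L), T_, TRUE)
  tgt <- c(1L, src[-T_]) * sample(c(1L, -1L), T_, TRUE, prob = c(0.99, 0.01))
  expect_gt(granger_pair(fake_traj(cbind(src, tgt)), 1, 2), 3)

  const <- fake_traj(cbind(sample(c(-1L, 1L), 500, TRUE), rep(1L, 500)))
  expect_warning(g0 <- granger_pair(const, 1, 2), "constant")
  expect_equal(g0, 0)

  # Gaussian approximation: delta / 2 within 20% of TE on the Ising chain
  net <- chain3_net()
  tr <- simulate_ising(net, 0.5, n_sweeps = 1e5, n_transient = 5000, seed = 12)
  for (pair in list(c(1, 2), c(2, 1), c(2, 3), c(3, 2))) {
    te <- transfer_entropy_pair(tr, pair[1], pair[2])
    gc <- granger_pair(tr, pair[1], pair[2])
    expect_lt(abs(gc / 2 - te) / te, 0.2)
  }
})

test_that("TE is symmetric within noise at beta 0", {
  net <- make_surrogate_connectome(12, seed = 13)
  tr <- simulate_ising(net, 0, n_sweeps = 1e5, n_transient = 100, seed = 14)
  fl <- flow_matrix(tr, net, "te")
  expect_lt(max(abs(fl$flows - t(fl$flows))), 1e-3)
})
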