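test_that("zero coupling gives independent fair spins", {
  net <- make_surrogate_connectome(20, seed = 2)
  tr <- simulate_ising(net, beta = 0, n_sweeps = 5000, n_transient = 100,
                       seed = 1)
  p_up <- colMeans(tr$spins == 1)
  se <- sqrt(0.25 / nrow(tr$spins))
  expect_true(all(abs(p_up - 0.5) < 3 * se))
  expect_true(all(tr$spins %in% c(-1L, 1L)))
})

test_that("identical arguments give identical trajectories; bad input errors", {
  net <- chain3_net()
  a <- simulate_ising(net, 0.4, "metropolis", 200, 50, seed = 9)
  b <- simulate_ising(net, 0.4, "metropolis", 200, 50, seed = 9)
  expect_identical(a$spins, b$spins)
  expect_error(simulate_ising(net, 0.4, "sequential", 200, 50, seed = 1),
               "unknown dynamics")
  expect_error(simulate_ising(net, -1, "glauber", 200, 50, seed = 1),
               "beta")
})

test_that("two coupled spins sample the exact Boltzmann alignment", {
  net <- pair_net()
  beta <- 3
  tr <- simulate_ising(net, beta, "glauber", 20000, 2000, seed = 7)
  bz <- boltzmann_probs(net$weights, beta)
  aligned_exact <- sum(bz$p[bz$states[, 1] == bz$states[, 2]])
  aligned_series <- as.numeric(tr$spins[, 1] == tr$spins[, 2])
  se <- batch_se(aligned_series)
  expect_lt(abs(mean(aligned_series) - aligned_exact), 3 * se)
})

test_that("one-sweep transition frequencies match the exact kernel on a chain", {
  net <- chain3_net()
  beta <- 0.5
  or <- glauber_sweep_matrix(net$weights, beta)
  tr <- simulate_ising(net, beta, "glauber", 60000, 2000, seed = 11)
  key <- apply(or$states, 1, paste, collapse = ",")
  obs_key <- apply(tr$spins, 1, paste, collapse = ",")
  idx <- match(obs_key, key)
  T_ <- length(idx)
  for (q in seq_len(8)) {
    from <- which(idx[-T_] == q)
    if (length(from) < 200) next
    emp <- tabulate(idx[from + 1L], 8) / length(from)
    se <- sqrt(pmax(or$Psweep[q, ] * (1 - or$Psweep[q, ]), 1e-12) /
                 length(from))
    expect_true(all(abs(emp - or$Psweep[q, ]) < 3 * se + 1e-3),
                info = paste("from state", q))
  }
})

test_that("all single-site dynamics sample the Boltzmann distribution", {
  net <- chain3_net()
  for (beta in c(0.2, 0.5, 1.0)) {
    bz <- boltzmann_probs(net$weights, beta)
    key <- apply(bz$states, 1, paste, collapse = ",")
    for (dyn in c("glauber", "metropolis", "heat_bath")) {
      tr <- simulate_ising(net, beta, dyn, 30000, 2000, seed = 13)
      idx <- match(apply(tr$spins, 1, paste, collapse = ","), key)
      for (q in seq_len(8)) {
        ind <- as.numeric(idx == q)
        se <- max(batch_se(ind), 1e-4)
        expect_lt(abs(mean(ind) - bz$p[q]), 3 * se + 2e-3)
      }
    }
  }
})

test_that("Wolff and Glauber agree on <|m|> on the 4x4 torus", {
  net <- make_lattice2d(4, periodic = TRUE)
  for (beta in c(0.3, 0.6)) {
    trg <- simulate_ising(net, beta, "glauber", 20000, 2000, seed = 3)
    trw <- simulate_ising(net, beta, "wolff", 20000, 2000, seed = 4)
    mg <- abs(rowMeans(trg$spins))
    mw <- abs(rowMeans(trw$spins))
    se <- sqrt(batch_se(mg)^2 + batch_se(mw)^2)
    expect_lt(abs(mean(mg) - mean(mw)), 3 * se)
  }
})

test_that("magnetisation grows with beta on the lattice", {
  net <- make_lattice2d(8, periodic = TRUE)
  m_lo <- thermo(simulate_ising(net, 0.1, n_sweeps = 3000, n_transient = 1000,
                                seed = 1), net)$mean_abs_magnetization
  m_hi <- thermo(simulate_ising(net, 1.0, n_sweeps = 3000, n_transient = 1000,
                                seed = 1), net)$mean_abs_magnetization
  expect_gt(m_hi, m_lo)
})

test_that("thermo matches exact two-spin Boltzmann averages and degenerate cases", {
  net <- pair_net()
  beta <- 0.4
  tr <- simulate_ising(net, beta, "glauber", 50000, 2000, seed = 21)
  th <- thermo(tr, net)
  bz <- boltzmann_probs(net$weights, beta)
  m <- rowMeans(bz$states)
  chi_exact <- beta * 2 * (sum(bz$p * m^2) - sum(bz$p * abs(m))^2)
  C_exact <- beta^2 * (sum(bz$p * bz$E^2) - sum(bz$p * bz$E)^2) / 2
  ms <- rowMeans(tr$spins)
  E <- trajectory_energy(tr, net)
  se_chi <- beta * 2 * sqrt(batch_se(ms^2)^2 + (2 * mean(abs(ms)) *
                                                  batch_se(abs(ms)))^2)
  se_C <- beta^2 / 2 * sqrt(batch_se(E^2)^2 + (2 * abs(mean(E)) *
                                                 batch_se(E))^2)
  expect_lt(abs(th$chi - chi_exact), 3 * se_chi)
  expect_lt(abs(th$heat_capacity - C_exact), 3 * se_C)

  # zero-variance and beta = 0 limits
  const <- fake_traj(matrix(1L, 100, 2), beta = 0.7)
  th0 <- thermo(const, net)
  expect_equal(th0$chi, 0)
  expect_equal(th0$heat_capacity, 0)
  tr0 <- simulate_ising(net, 0, n_sweeps = 500, n_transient = 10, seed = 1)
  expect_equal(thermo(tr0, net)$chi, 0)
  expect_error(thermo(tr, make_lattice2d(3)), "dimensions differ")
})

test_that("flip times: alternating, constant and free-spin cases", {
  alt <- fake_traj(cbind(rep(c(1L, -1L), 50)))
  expect_equal(flip_times(alt), 1)
  expect_identical(flip_times(fake_traj(matrix(1L, 50, 1))), Inf)

  # beta = 0: inter-flip intervals are geometric with mean 1/p,
  # p = (1 - (1 - 1/N)^N) / 2 for random-site updates
  net <- make_surrogate_connectome(10, seed = 4)
  tr <- simulate_ising(net, 0, n_sweeps = 20000, n_transient = 10, seed = 6)
  p <- (1 - (1 - 1 / 10)^10) / 2
  tau <- flip_times(tr)
  n_flips <- 20000 * p
  se <- (sqrt(1 - p) / p) / sqrt(n_flips)
  expect_true(all(abs(tau - 1 / p) < 3 * se))
})
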