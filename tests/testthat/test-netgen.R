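check_network_invariants <- function(net) {
  expect_true(isSymmetric(net$weights))
  expect_true(all(diag(net$weights) == 0))
  expect_true(all(net$weights >= 0))
  expect_identical(nrow(net$weights), net$n_nodes)
}

test_that("square lattice has the right size, degrees and unit weights", {
  net <- make_lattice2d(4, periodic = TRUE)
  check_network_invariants(net)
  expect_identical(net$n_nodes, 16L)
  deg <- rowSums(net$weights > 0)
  expect_true(all(deg == 4))
  expect_equal(sum(net$weights > 0) / 2, 32)  # 2 L^2 bonds on the torus

  open3 <- make_lattice2d(3, periodic = FALSE)
  deg3 <- rowSums(open3$weights > 0)
  expect_equal(sort(unique(deg3)), c(2, 3, 4))
  expect_equal(deg3[5], 4)          # centre of the 3x3 grid
  expect_equal(deg3[c(1, 3, 7, 9)], rep(2, 4))  # corners

  big <- make_lattice2d(16, periodic = TRUE)
  expect_true(all(big$weights[big$weights > 0] == 1))
  expect_error(make_lattice2d(1), "L must be")
})

test_that("deterministic scale-free graph follows the three-copy recursion", {
  expect_identical(make_deterministic_scale_free(0)$n_nodes, 1L)
  expect_equal(sum(make_deterministic_scale_free(0)$weights), 0)
  for (g in 0:5)
    expect_identical(make_deterministic_scale_free(g)$n_nodes,
                     as.integer(3^g))
  net <- make_deterministic_scale_free(4)
  check_network_invariants(net)
  expect_identical(net$n_nodes, 81L)
  # E_g = 3 E_{g-1} + 2^g: 2, 10, 38, 130; root degree sum(2^k) = 30
  e_expected <- 0
  for (g in 1:4) e_expected <- 3 * e_expected + 2^g
  expect_equal(sum(net$weights > 0) / 2, e_expected)
  expect_equal(e_expected, 130)
  expect_equal(sum(net$weights[1, ] > 0), 30)
  expect_true(all(net$weights[net$weights > 0] == 1))
  expect_error(make_deterministic_scale_free(-1), "non-negative")
})

test_that("surrogate connectome is reproducible, modular and fat-tailed", {
  a <- make_surrogate_connectome(66, seed = 7)
  b <- make_surrogate_connectome(66, seed = 7)
  expect_identical(a$weights, b$weights)  # bitwise determinism
  check_network_invariants(a)
  expect_identical(sort(unique(a$module_labels)), 1:2)

  # zero inter-module density gives block-diagonal weights
  blk <- make_surrogate_connectome(66, inter_density = 0, seed = 3)
  inter <- outer(blk$module_labels, blk$module_labels, "!=")
  expect_true(all(blk$weights[inter] == 0))

  # log-normal weights make strengths more right-skewed than the same
  # backbone with uniform weights
  net <- make_surrogate_connectome(66, intra_density = 0.3,
                                   inter_density = 0.05, seed = 1)
  s_lognorm <- rowSums(net$weights)
  Wu <- (net$weights > 0) * mean(net$weights[net$weights > 0])
  s_unif <- rowSums(Wu)
  expect_gt(skewness(s_lognorm), 0)
  expect_gt(skewness(s_lognorm), skewness(s_unif))
})

test_that("surrogate generation fails cleanly when connectivity is unreachable", {
  expect_error(
    make_surrogate_connectome(30, n_modules = 2, intra_density = 0.01,
                              inter_density = 0.01, seed = 1,
                              max_retries = 3),
    "retry budget")
})

test_that("degree-preserving shuffle keeps degrees and the weight multiset", {
  net <- make_surrogate_connectome(66, seed = 11)
  deg0 <- sort(rowSums(net$weights > 0))
  w0 <- sort(net$weights[upper.tri(net$weights) & net$weights > 0])
  for (s in 1:100) {
    sh <- degree_preserving_shuffle(net, seed = s)
    expect_identical(sort(rowSums(sh$weights > 0)), deg0)
  }
  sh <- degree_preserving_shuffle(net, seed = 1)
  expect_equal(sort(sh$weights[upper.tri(sh$weights) & sh$weights > 0]), w0)
  expect_false(identical(sh$weights, net$weights))

  # the triangle admits no double-edge swap: unchanged, with a warning
  tri <- weighted_network(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3))
  expect_warning(out <- degree_preserving_shuffle(tri, seed = 1), "no valid")
  expect_identical(out$weights, tri$weights)
})

test_that("network text round-trips preserve weights exactly", {
  net <- make_surrogate_connectome(66, seed = 5)
  for (fmt in c("dense", "edgelist")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_network(net, f, fmt)
    back <- read_network(f, fmt)
    expect_identical(back$weights, net$weights)
  }
})

test_that("malformed network files are rejected with located errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 1 0", "2 0 1", "0 1 0"), f)  # [1,2] != [2,1]
  expect_error(read_network(f, "dense"), "not symmetric")
  writeLines(c("0 1", "1 0 2", "0 1 0"), f)
  expect_error(read_network(f, "dense"), "not square")
  writeLines(c("0\t1\t2.5", "1\t1\t0.3"), f)
  expect_error(read_network(f, "edgelist"), "self-loop in edge list at line 2")
  writeLines(c("0\t1\t-2.5"), f)
  expect_error(read_network(f, "edgelist"), "negative weight")
})

test_that("a single edge-list line builds a 2-node symmetric network", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("0 1 2.5", f)
  net <- read_network(f, "edgelist")
  expect_identical(net$n_nodes, 2L)
  expect_equal(net$weights[1, 2], 2.5)
  expect_equal(net$weights[2, 1], 2.5)
})
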