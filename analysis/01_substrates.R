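#!/usr/bin/env Rscript
# Builds the network substrates used throughout the analysis and records
# their basic structure: the 16x16 torus (exactly solvable control), the
# 81-node deterministic scale-free graph, the 66-node two-hemisphere
# surrogate connectome, and a degree-preserving shuffle of the surrogate.
#
# Outputs: results/substrates/*.txt (edge lists), results/substrates/summary.tsv

library(isingflow)

out_dir <- "results/substrates"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

nets <- list(
  lattice16 = make_lattice2d(16, periodic = TRUE),
  dsf81 = make_deterministic_scale_free(4),
  surrogate66 = make_surrogate_connectome(66, seed = 101)
)
nets$surrogate66_shuffled <- degree_preserving_shuffle(nets$surrogate66,
                                                       seed = 202)

rows <- lapply(names(nets), function(nm) {
  net <- nets[[nm]]
  write_network(net, file.path(out_dir, paste0(nm, ".txt")), "edgelist")
  if (!is.null(net$module_labels))
    writeLines(as.character(net$module_labels),
               file.path(out_dir, paste0(nm, "_modules.txt")))
  s <- node_strength(net)
  data.frame(network = nm, n_nodes = net$n_nodes,
             n_edges = sum(net$weights > 0) / 2,
             mean_strength = mean(s), max_strength = max(s),
             strength_skewness = mean((s - mean(s))^3) /
               mean((s - mean(s))^2)^1.5)
})
summary <- do.call(rbind, rows)
write.table(summary, file.path(out_dir, "summary.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
print(summary, digits = 3)

skew <- function(x) mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5
surr <- nets$surrogate66
s_unif <- rowSums((surr$weights > 0) * mean(surr$weights[surr$weights > 0]))
cat("\nThe surrogate's strengths are right-skewed",
    sprintf("(skewness %.2f, vs %.2f for uniform weights on the same backbone):",
            skew(node_strength(surr)), skew(s_unif)),
    "\nthe log-normal weights, not the wiring, carry the heterogeneity",
    "that emulates fibre-density variation in structural connectomes.\n")
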